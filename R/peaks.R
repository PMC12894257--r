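# Peak tables, coordinate-space conversion and statistic conversion.

# Lancaster icbm2tal affine (SPM flavor): maps MNI (ICBM152) mm to
# Talairach mm. Talairach -> MNI uses its inverse. A single fixed affine is
# an approximation of the full piecewise transform; adequate here because
# synthetic peaks are generated in MNI space and only round-tripped.
.icbm_spm2tal <- matrix(c(
  0.9254,  0.0024, -0.0118, -1.0207,
 -0.0048,  0.9316, -0.0871, -1.7667,
  0.0152,  0.0883,  0.8924,  4.0926,
  0,       0,       0,       1
), nrow = 4, byrow = TRUE)

#' Talairach to MNI coordinate conversion
#'
#' Applies the inverse of the Lancaster icbm2tal affine. Deterministic;
#' MNI-space inputs should not be passed through this function.
#'
#' @param xyz length-3 vector or n x 3 matrix of Talairach mm coordinates.
#' @return coordinates in MNI mm, same shape as the input.
#' @export
tal_to_mni <- function(xyz) {
  one_row <- is.null(dim(xyz))
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  stopifnot(all(is.finite(xyz)))
  inv <- solve(.icbm_spm2tal)
  out <- t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4L])
  if (one_row) drop(out) else out
}

#' @rdname tal_to_mni
#' @export
mni_to_tal <- function(xyz) {
  one_row <- is.null(dim(xyz))
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  out <- t(.icbm_spm2tal[1:3, 1:3] %*% t(xyz) + .icbm_spm2tal[1:3, 4L])
  if (one_row) drop(out) else out
}

#' Convert a reported peak statistic to a t-value
#'
#' Peak statistics are reported as t, z or (two-tailed) p depending on the
#' study; downstream effect-size reconstruction needs t. z maps to t by
#' quantile matching through the standard-normal CDF; two-tailed p maps to
#' |t| through the inverse survival function. The sign of a p-derived t is
#' taken from `sign`.
#'
#' @param value the reported statistic.
#' @param from_kind "t", "z" or "p".
#' @param df degrees of freedom (n1 + n2 - 2); required for z and p.
#' @param sign +1 for a gray-matter increase, -1 for a decrease; used only
#'   for p-derived values (t and z carry their own sign).
#' @return a t-value with df degrees of freedom.
#' @export
convert_stat <- function(value, from_kind = c("t", "z", "p"), df = NULL,
                         sign = 1) {
  from_kind <- match.arg(from_kind)
  stopifnot(is.finite(value))
  if (from_kind == "t") return(value)
  if (is.null(df) || !is.finite(df) || df < 1) {
    stop("df is required to convert z or p to t")
  }
  if (from_kind == "z") {
    # quantile matching in the upper tail of |z| to keep precision there
    lp <- stats::pnorm(abs(value), lower.tail = FALSE, log.p = TRUE)
    return(base::sign(value) *
             stats::qt(lp, df = df, lower.tail = FALSE, log.p = TRUE))
  }
  if (value <= 0 || value > 1) stop("p-value must lie in (0, 1]")
  abs_t <- stats::qt(value / 2, df = df, lower.tail = FALSE)
  as.numeric(sign) * abs_t
}

#' Read a per-study peak table
#'
#' The table is delimited text with one row per reported peak and columns
#' `study, n_patients, n_controls, x, y, z, stat, stat_kind, space, sign`.
#' Talairach coordinates are converted to MNI and all statistics to t.
#' Studies with seven or fewer participants in either group are rejected,
#' mirroring standard CBMA inclusion rules.
#'
#' @param path CSV/TSV file path (separator sniffed from the header line).
#' @return a `study_set`: list of studies, each with id, group sizes and a
#'   peaks data.frame (x, y, z in MNI mm; t-value).
#' @export
read_peak_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("study", "n_patients", "n_controls", "x", "y", "z",
                "stat", "stat_kind", "space", "sign")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("peak table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  study_set_from_df(df)
}

#' Build a study set from a peak data.frame
#' @param df data.frame with the columns of [read_peak_table()].
#' @export
study_set_from_df <- function(df) {
  bad_p <- df$stat_kind == "p" & (df$stat <= 0 | df$stat > 1)
  if (any(bad_p)) {
    stop(sprintf("%d peak(s) report stat_kind=p outside (0, 1]", sum(bad_p)))
  }
  if (!all(df$space %in% c("MNI", "Talairach"))) {
    stop("space must be 'MNI' or 'Talairach'")
  }
  if (!all(df$sign %in% c("increase", "decrease"))) {
    stop("sign must be 'increase' or 'decrease'")
  }
  studies <- lapply(split(df, df$study), function(s) {
    n1 <- unique(s$n_patients)
    n2 <- unique(s$n_controls)
    stopifnot(length(n1) == 1L, length(n2) == 1L)
    if (n1 <= 7 || n2 <= 7) {
      stop(sprintf(
        "study '%s' excluded: a group has seven or fewer individuals (n_patients=%d, n_controls=%d)",
        s$study[1], n1, n2
      ))
    }
    xyz <- as.matrix(s[, c("x", "y", "z")])
    tal <- s$space == "Talairach"
    if (any(tal)) xyz[tal, ] <- tal_to_mni(xyz[tal, , drop = FALSE])
    sgn <- ifelse(s$sign == "increase", 1, -1)
    tval <- vapply(seq_len(nrow(s)), function(i) {
      convert_stat(s$stat[i], s$stat_kind[i], df = n1 + n2 - 2,
                   sign = sgn[i])
    }, numeric(1))
    list(id = as.character(s$study[1]), n_patients = n1, n_controls = n2,
         peaks = data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            t = tval))
  })
  structure(list(studies = unname(studies)), class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  np <- vapply(x$studies, function(s) nrow(s$peaks), integer(1))
  cat(sprintf("<study_set> %d studies, %d peaks\n",
              length(x$studies), sum(np)))
  invisible(x)
}

#' Write a study set back to a peak CSV
#' @param ss a `study_set` (peaks already in MNI / t form).
#' @param path output CSV.
#' @export
write_peak_table <- function(ss, path) {
  rows <- do.call(rbind, lapply(ss$studies, function(s) {
    data.frame(study = s$id, n_patients = s$n_patients,
               n_controls = s$n_controls,
               x = s$peaks$x, y = s$peaks$y, z = s$peaks$z,
               stat = s$peaks$t, stat_kind = "t", space = "MNI",
               sign = ifelse(s$peaks$t >= 0, "increase", "decrease"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
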