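# Shared fixtures: compact grids and small synthetic datasets so tests
# stay fast while exercising the full pipeline geometry.

# brain-like mask on a coarse lattice; ~7.5k voxels at 6 mm
test_grid <- function(voxel = 6) {
  ellipsoid_mask(make_grid(voxel))
}

# one-voxel grid for closed-form statistics at a single location
point_grid <- function() {
  make_grid(voxel_size = 2, bbox = rbind(c(0, 0, 0), c(0, 0, 0)))
}

# small peak table data.frame with valid defaults
peak_df <- function(study = "S1", n1 = 20, n2 = 22, x = 10, y = -20,
                    z = 30, stat = 3, stat_kind = "t", space = "MNI",
                    sign = "increase") {
  data.frame(study = study, n_patients = n1, n_controls = n2, x = x,
             y = y, z = z, stat = stat, stat_kind = stat_kind,
             space = space, sign = sign)
}
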