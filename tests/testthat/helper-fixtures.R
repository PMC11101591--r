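# Shared fixtures: all built in code at test time.

# A horizontal slab of bone (rows 1..bone_rows) over marrow, at lambda um.
make_slab_grid <- function(nr = 300, nc = 400, bone_rows = 150, lambda = 1) {
  lab <- matrix(0L, nr, nc)
  lab[seq_len(bone_rows), ] <- 1L
  label_grid(lab, lambda)
}

# A filled disc of bone centred in marrow.
make_disc_grid <- function(n = 201, radius = 50, lambda = 1) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  label_grid(matrix(as.integer(d <= radius), n, n), lambda)
}

# Simulation state on a slab with uniform initial mineralisation.
make_slab_state <- function(nr = 300, nc = 400, bone_rows = 150, lambda = 1,
                            Tsec = 8, alpha0 = 0.70, ...) {
  grid <- make_slab_grid(nr, nc, bone_rows, lambda)
  law <- calibrate_mineralisation_law(Tsec)
  params <- remodelling_params(...)
  sim_state(grid, law, params, alpha0 = alpha0)
}

# Brute-force perimeter oracle: bone pixels with a 4-adjacent marrow pixel
# (frame does not count as marrow).
perimeter_oracle <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  out <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (lab[i, j] == 0L) next
    nb <- c(
      if (i > 1) lab[i - 1, j],
      if (i < nr) lab[i + 1, j],
      if (j > 1) lab[i, j - 1],
      if (j < nc) lab[i, j + 1]
    )
    if (any(nb == 0L)) out <- c(out, i + (j - 1L) * nr)
  }
  out
}

# A small, fast simulation configuration: 0.64 mm^2 domain at 4 um with
# thinner struts so several fit the small lattice.
small_config <- function(..., record_every = 7) {
  simulation_config(width_px = 200, height_px = 200, lambda = 4,
                    target_f_Bm = 0.42, thickness_range = c(100, 200),
                    record_every = record_every, ...)
}
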