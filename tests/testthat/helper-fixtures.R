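# Shared fixtures built in code at test time.

insulin_like_grid <- function(subdivision = 3) {
  miller_grid(cubic_cell(79.48), subdivision, "I", "m-3")
}

# simulation config with all artifacts off unless overridden; small sizes
# are chosen per test
sim_config_quiet <- function(...) {
  args <- list(amp_a = 0, amp_b = 0, amp_c = 0, chip_drop = 0, edge_drop = 0)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

# brute-force inverse-variance merge per asymmetric-unit voxel, used as the
# independent oracle for merge_scaled
oracle_merge <- function(obs, m = 1, o = 0) {
  m <- rep_len(m, nrow(obs)); o <- rep_len(o, nrow(obs))
  key <- paste(obs$asu_i, obs$asu_j, obs$asu_k)
  out <- lapply(unique(key), function(k) {
    rows <- which(key == k & obs$sigma > 0)
    if (!length(rows)) return(NULL)
    iscl <- (obs$I[rows] - o[rows]) / m[rows]
    w <- (m[rows] / obs$sigma[rows])^2
    data.frame(key = k, I = sum(w * iscl) / sum(w), sigma = 1 / sqrt(sum(w)),
               n_obs = length(rows))
  })
  do.call(rbind, out)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# independent enumeration oracle for the diffuse-voxel count: counts Bragg
# nodes by direct modular arithmetic over one centering period
oracle_diffuse_count <- function(subdivision, centering) {
  period <- if (centering == "P") 1L else 2L
  side <- period * subdivision
  n_total <- side^3
  n_bragg <- 0L
  for (h in 0:(period - 1)) for (k in 0:(period - 1)) for (l in 0:(period - 1)) {
    allowed <- switch(centering,
                      P = TRUE,
                      I = (h + k + l) %% 2 == 0,
                      F = (h %% 2 == k %% 2) && (k %% 2 == l %% 2),
                      C = (h + k) %% 2 == 0)
    if (allowed) n_bragg <- n_bragg + 1L
  }
  (n_total - n_bragg) / n_bragg
}
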