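# Small shared synthetic world, built once per test run.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dm <- generate_districts(6, seed = 11, extent = c(0, 0, 100, 160),
                               total_population = 1e6)
      f <- generate_true_fields(dm, seed = 12, cell_size = 4)
      wc <- sample_wells(f, dm, 300, seed = 13)
      wm <- apply_missingness(wc, seed = 14)
      cache <<- list(districts = dm, fields = f, wells_complete = wc,
                     wells = wm, standards = load_standards())
    }
    cache
  }
})

# well table wrapper for raw point data
as_well_table <- function(x, y, ...) {
  df <- data.frame(well_id = sprintf("W%03d", seq_along(x)), x = x, y = y, ...)
  class(df) <- c("well_table", "data.frame")
  df
}

# brute-force ordinary kriging at a single query: direct solve of the
# semivariance system augmented with the unbiasedness constraint
ok_oracle <- function(x, y, z, vm, qx, qy) {
  n <- length(x)
  G <- aquahazard:::vgm_gamma(vm, as.matrix(stats::dist(cbind(x, y))))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  g0 <- aquahazard:::vgm_gamma(vm, sqrt((x - qx)^2 + (y - qy)^2))
  w <- solve(A, c(g0, 1))
  list(pred = sum(w[seq_len(n)] * z), var = sum(w * c(g0, 1)),
       weights = w[seq_len(n)])
}
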