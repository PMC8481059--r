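# Shared fixtures: the bundled case studies, a small fixed toy data set for
# brute-force oracle checks, and the exhaustive grid search used as the
# optimiser-independent oracle.

jute <- eiw_dataset("jute")
carbon <- eiw_dataset("carbon")

sample_of <- function(data, role) data$value[data$role == role]

# fixed 4+4-point toy sample for grid-oracle checks (kept tiny so an
# exhaustive 3-D search stays cheap)
toy_data <- ss_data(
  x = c(0.8, 1.5, 2.3, 3.1),
  y = c(0.6, 1.2, 1.9, 2.7)
)

# Exhaustive log-space grid search of a joint objective.  Returns the best
# grid point and the grid value; `half_width` is the log-space half-width of
# the box around `center`, `len` the number of points per axis.
grid_search_oracle <- function(f, center = c(1, 1, 1), half_width = log(20),
                               len = 31) {
  gr <- function(c0) exp(seq(log(c0) - half_width, log(c0) + half_width,
                             length.out = len))
  g1 <- gr(center[1]); g2 <- gr(center[2]); g3 <- gr(center[3])
  best <- list(value = Inf, par = c(NA, NA, NA))
  for (b in g3) {
    for (t2 in g2) {
      vals <- vapply(g1, function(t1) f(t1, t2, b), numeric(1))
      i <- which.min(vals)
      if (vals[i] < best$value) {
        best <- list(value = vals[i], par = c(g1[i], t2, b))
      }
    }
  }
  best$spacing <- 2 * half_width / (len - 1)
  best
}
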