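# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a mid-growth easy-panel frame with truth mask
easy_frame <- function(day = 15, class = 1, seed = 11) {
  cached(sprintf("easy_%d_%d_%d", day, class, seed),
         render_frame(easy_accession_panel()[[class]], day = day,
                      canvas_size = 128, seed = seed))
}

# small in-memory dataset: 4 easy classes x 2 plants x 12 days at 128 px
small_dataset <- function() {
  cached("small_ds",
         generate_sequences(easy_accession_panel(), n_plants_per_class = 2,
                            n_days = 12, canvas_size = 128, seed = 21))
}

# random blob mask for property tests
random_blob <- function(seed, side = 48) {
  set.seed(seed)
  m <- matrix(FALSE, side, side)
  n_discs <- sample(2:4, 1)
  for (i in seq_len(n_discs)) {
    cy <- runif(1, side * 0.3, side * 0.7); cx <- runif(1, side * 0.3, side * 0.7)
    r <- runif(1, 4, 9)
    for (rr in max(1, floor(cy - r)):min(side, ceiling(cy + r)))
      for (cc in max(1, floor(cx - r)):min(side, ceiling(cx + r)))
        if ((rr - cy)^2 + (cc - cx)^2 <= r^2) m[rr, cc] <- TRUE
  }
  m
}
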