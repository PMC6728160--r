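# Small deterministic fixtures shared across tests.

tiny_volume <- function(dims = c(8L, 8L, 4L), spacing = c(1.25, 1.25, 2),
                        seed = 1) {
  with_seed(seed, cmr_volume(array(runif(prod(dims)), dims), spacing))
}

tiny_labelmap <- function(dims = c(8L, 8L, 4L), spacing = c(1, 1, 1),
                          n_classes = 5L, seed = 1) {
  with_seed(seed, cmr_labelmap(array(sample(0:(n_classes - 1L), prod(dims), TRUE),
                                     dims), spacing, n_classes = n_classes))
}

# six non-coplanar named landmark points
tiny_points <- function(seed = 1, scale = 20) {
  pts <- with_seed(seed, matrix(rnorm(18, 0, scale), 6L, 3L))
  rownames(pts) <- landmark_names()
  pts
}

# a small heart for registration unit tests where anatomy realism is not the
# point (the acceptance suite exercises the full-size default)
compact_spec <- function(...) {
  args <- modifyList(list(grid_dims = c(48L, 48L, 30L), lv_endo_r = 9,
                          lv_epi_r = 15, extent = 46, rv_shift = 14,
                          rv_r = c(16, 13), rvw_thickness = 3), list(...))
  do.call(phantom_spec, args)
}

default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom()
    cache
  }
})
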