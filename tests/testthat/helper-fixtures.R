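# Shared expensive fixtures, computed once per test run.
# The "standard phantom" is the generator's default world: 32x32x8,
# WM 0.10/0.85/0.05 @ 20/80/1000 ms, flip field 150-180 deg, first-echo
# SNR 200, Gaussian noise, seed 11.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

standard_phantom <- function() {
  memo("phantom", function() generate_phantom(phantom_spec(seed = 11L)))
}

standard_phantom_fit <- function() {
  memo("fit", function() {
    ph <- standard_phantom()
    fit_volume(ph$echoes, ph$tissue_labels > 0L, ph$spec$params, t2_grid())
  })
}

standard_phantom_maps <- function() {
  memo("maps", function() assemble_maps(standard_phantom_fit()))
}

# noiseless twin of the standard phantom, fitted on a thinned WM mask
# (every 2nd voxel in-plane) to keep the run inside the time budget
noiseless_phantom <- function() {
  memo("phantom0", function() {
    generate_phantom(phantom_spec(seed = 11L, snr = Inf))
  })
}

noiseless_phantom_fit <- function() {
  memo("fit0", function() {
    ph <- noiseless_phantom()
    mask <- ph$tissue_labels > 0L
    d <- dim(mask)
    thin <- array(FALSE, d)
    thin[seq(1, d[1], 2), seq(1, d[2], 2), ] <- TRUE
    fit_volume(ph$echoes, mask & thin, ph$spec$params, t2_grid())
  })
}

noiseless_phantom_maps <- function() {
  memo("maps0", function() assemble_maps(noiseless_phantom_fit()))
}
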