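# Shared fixtures and independent oracles.  All fixtures are built in code;
# nothing is read from disk.

flat_spectrum <- function(value = 0.5, wl = 1000:1100) {
  spectrum(wl, rep(value, length(wl)))
}

# random piecewise-linear reflectance sampled on a 1 nm grid; knots are a
# random subset of the grid so the sampled values determine the underlying
# function exactly
random_pw_spectrum <- function(wl = 1000:1100, n_knots = 6,
                               lo = 0.1, hi = 0.9) {
  knots <- sort(c(wl[1], wl[length(wl)],
                  sample(wl[-c(1, length(wl))], n_knots - 2)))
  kv <- runif(length(knots), lo, hi)
  spectrum(wl, approx(knots, kv, xout = wl)$y)
}

small_dataset <- function(n = 4, wl = seq(400, 900, by = 10), seed = 7) {
  set.seed(seed)
  m <- t(replicate(n, 0.2 + 0.3 * exp(-(wl - 650)^2 / 2e4) + runif(1, 0, 0.1)))
  spectral_dataset(wl, m, sprintf("s%d", seq_len(n)))
}

# --- brute-force continuum-removal oracle -----------------------------------
# Dense scan (0.01 nm plus all grid wavelengths) over the piecewise-linear
# interpolant of the sampled spectrum: chord from the in-zone endpoints, band
# depth 1 - R/chord, maximum depth, and width at half depth via linear
# interpolation between adjacent dense points, walking outward from the
# deepest point.
bf_continuum_oracle <- function(wl, v, bounds, step = 0.01) {
  inz <- which(wl >= bounds[1] & wl <= bounds[2])
  ws <- wl[inz[1]]; we <- wl[inz[length(inz)]]
  dense <- sort(unique(c(seq(ws, we, by = step), wl[inz])))
  xd <- approx(wl, v, xout = dense)$y
  chord <- approx(c(ws, we), c(v[inz[1]], v[inz[length(inz)]]),
                  xout = dense)$y
  bd <- 1 - xd / chord
  mbd <- max(0, max(bd))
  if (mbd == 0) return(list(MBD = 0, W = NA_real_))
  i0 <- which.max(bd)[1]
  half <- mbd / 2
  cross <- function(dir) {
    i <- i0
    repeat {
      j <- i + dir
      if (j < 1 || j > length(dense)) return(dense[i])
      if (bd[j] <= half) {
        if (bd[j] == bd[i]) return(dense[j])
        return(dense[i] + (half - bd[i]) * (dense[j] - dense[i]) /
                 (bd[j] - bd[i]))
      }
      i <- j
    }
  }
  list(MBD = mbd, W = cross(1) - cross(-1))
}

# --- scikit-learn PLSR oracle ----------------------------------------------
# Batches several problems through one python call; returns a list of
# prediction vectors.  PLSRegression(scale=False) is mean-centred NIPALS,
# the same model family as fit_plsr().
sklearn_pls_predict <- function(problems) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  infile <- file.path(dir, "problems.json")
  outfile <- file.path(dir, "preds.json")
  jsonlite::write_json(problems, infile, digits = NA, auto_unbox = FALSE)
  script <- file.path(dir, "pls_oracle.py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from sklearn.cross_decomposition import PLSRegression",
    "probs = json.load(open(sys.argv[1]))",
    "out = []",
    "for p in probs:",
    "    X = np.array(p['X']); y = np.array(p['y'])",
    "    m = PLSRegression(n_components=int(p['ncomp'][0]), scale=False)",
    "    out.append(m.fit(X, y).predict(X).ravel().tolist())",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, infile, outfile))
  stopifnot(status == 0L)
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}
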