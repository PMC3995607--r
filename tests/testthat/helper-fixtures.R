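# Shared fixtures and independent oracles.  Phantoms are cached per key so
# expensive volumes are generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small, fast phantom for module-level tests
small_spec <- function(seed = 7, ...) {
  phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = c(3, 3, 3),
               seed = seed, ...)
}

phantom_small_clean <- function() {
  cached("small_clean", generate_phantom(small_spec()))
}

phantom_small_artifacts <- function() {
  cached("small_artifacts",
         generate_phantom(small_spec(include_cardiac_spillover = TRUE,
                                     include_tumor = TRUE,
                                     include_diaphragm_coldspot = TRUE)))
}

segmented_small_clean <- function() {
  cached("seg_small_clean", {
    ph <- phantom_small_clean()
    par <- segment_lung_parenchyma(ph$ct)
    aw <- extract_central_airway(ph$ct, par)
    list(parenchyma = par, airway = aw,
         roi = finalize_lung_roi(par, aw))
  })
}

# independent percentile oracle: explicit sort + rank interpolation at
# rank 1 + (p/100)(n-1)
oracle_percentile <- function(values, p) {
  x <- sort(values)
  n <- length(x)
  h <- 1 + (p / 100) * (n - 1)
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# independent AUC oracle: pairwise concordance count over all
# positive-negative pairs (ties count 1/2)
oracle_auc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  pos <- scores[y]; neg <- scores[!y]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent product-limit oracle (no ties assumed beyond exact equality)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1; out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

ref_csv <- function(name) {
  read.csv(system.file("extdata", name, package = "petrp"),
           stringsAsFactors = FALSE)
}
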