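# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state; the caller's .Random.seed is
# restored afterwards so package functions never clobber user randomness.
with_seed_ <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Fraction of pair margins ranked correctly; exact ties count half.
margin_accuracy <- function(margins) {
  if (!length(margins)) return(NA_real_)
  (sum(margins > 0) + 0.5 * sum(margins == 0)) / length(margins)
}

# Constraint metadata for a feature subset: sign (+1 abnormal, -1 normal) and
# ordinal chains (index vectors, low to high frequency, coefficient
# non-increasing along each chain).
constraint_meta <- function(features, vocab = eeg_vocabulary()) {
  pol <- vocab$polarity[match(features, vocab$feature)]
  sgn <- ifelse(pol == "abnormal", 1, -1)
  chains <- lapply(ordinal_groups(vocab), function(g) {
    idx <- match(intersect(g, features), features)
    idx[!is.na(idx)]
  })
  chains <- chains[vapply(chains, length, integer(1)) > 1]
  list(sign = sgn, chains = unname(chains))
}

# Euclidean projection onto the constraint cone: per ordinal chain a bounded
# non-increasing isotonic regression (PAVA, then clipping -- exact because the
# sign bounds are themselves monotone along each chain), plus sign clipping
# for features outside any chain.
project_cone <- function(w, meta) {
  in_chain <- rep(FALSE, length(w))
  for (idx in meta$chains) {
    in_chain[idx] <- TRUE
    v <- w[idx]
    v <- if (length(v) > 1) -stats::isoreg(seq_along(v), -v)$yf else v
    w[idx] <- ifelse(meta$sign[idx] > 0, pmax(v, 0), pmin(v, 0))
  }
  loose <- !in_chain
  w[loose] <- ifelse(meta$sign[loose] > 0, pmax(w[loose], 0), pmin(w[loose], 0))
  w
}
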