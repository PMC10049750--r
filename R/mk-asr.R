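# Two-state Mk models on a fixed tree: pruning likelihood, ML rate fits,
# AICc selection, marginal ancestral "scaled likelihoods" and the
# proportional-likelihood significance rule.

#' Construct a two-state Markov rate model
#'
#' An `ER` model has a single symmetric rate `q` (for two states ER is
#' identical to the symmetrical model); an `ARD` model has distinct forward
#' (`q01`) and reverse (`q10`) rates.  State 0 conventionally codes indirect
#' development, state 1 direct development.
#'
#' @param kind `"ER"` or `"ARD"`.
#' @param q single rate for ER, transitions per unit branch length.
#' @param q01,q10 forward/reverse rates for ARD.
#' @return An object of class `ppy_rate_model` with elements `kind`, `q01`,
#'   `q10` and free-parameter count `K`.
#' @examples
#' rate_model("ER", q = 0.1)
#' rate_model("ARD", q01 = 0.2, q10 = 0.05)
#' @export
rate_model <- function(kind = c("ER", "ARD"), q = NULL, q01 = NULL, q10 = NULL) {
  kind <- match.arg(kind)
  if (kind == "ER") {
    if (is.null(q)) stop("ER model requires `q`")
    if (q < 0) stop("rates must be >= 0")
    q01 <- q10 <- q
    K <- 1L
  } else {
    if (is.null(q01) || is.null(q10)) stop("ARD model requires `q01` and `q10`")
    if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
    K <- 2L
  }
  structure(list(kind = kind, q01 = q01, q10 = q10, K = K),
            class = "ppy_rate_model")
}

#' Transition probability matrix of the two-state Mk process
#'
#' Closed form of `expm(Q t)` for the generator
#' `Q = [[-q01, q01], [q10, -q10]]`.  Rows index the starting state
#' (0 then 1) and sum to 1.  For ER, `P[1,1] = 0.5 (1 + exp(-2 q t))`.
#'
#' @param model a [rate_model()].
#' @param t branch length, `t >= 0`.
#' @return 2x2 numeric matrix with dimnames `c("0","1")`.
#' @export
transition_matrix <- function(model, t) {
  if (!inherits(model, "ppy_rate_model")) stop("`model` must be a ppy_rate_model")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length `t` must be a single non-negative number")
  P <- mk_pmat(model$q01, model$q10, t)
  dimnames(P) <- list(c("0", "1"), c("0", "1"))
  P
}

# scalar closed form, no validation (hot path)
mk_pmat <- function(q01, q10, t) {
  s <- q01 + q10
  if (s <= 0 || t == 0) return(diag(2))
  e <- exp(-s * t)
  pi0 <- q10 / s
  pi1 <- q01 / s
  matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
           pi1 * (1 - e), pi1 + pi0 * e), 2L, 2L)
}

# Tip observations -> 2-column partial-likelihood matrix.
# Accepts a named vector over tips with values in
# {0, 1, "indirect", "direct", "both", "unknown", NA} or a ppy_traits table.
# "both" and "unknown" receive equal likelihood (1,1) for both states, the
# convention of the tooling this module re-implements.
tip_partials <- function(traits, tip_labels) {
  if (inherits(traits, "ppy_traits"))
    traits <- stats::setNames(traits$observation, traits$tip)
  if (is.null(names(traits))) stop("`traits` must be named by tip label")
  missing_tips <- setdiff(tip_labels, names(traits))
  if (length(missing_tips))
    stop("no trait observation for tips: ", paste(missing_tips, collapse = ", "))
  obs <- as.character(traits[tip_labels])
  L <- matrix(0, length(tip_labels), 2L)
  for (i in seq_along(obs)) {
    L[i, ] <- switch(ifelse(is.na(obs[i]), "unknown", obs[i]),
      "0" = , "indirect" = c(1, 0),
      "1" = , "direct"   = c(0, 1),
      "both" = , "unknown" = , "?" = c(1, 1),
      stop("unrecognized trait observation: ", obs[i]))
  }
  L
}

# Preprocess a phylo object for repeated pruning passes.
mk_tree_data <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  po <- ape::reorder.phylo(tree, "postorder")
  list(tree = po, edge = po$edge, len = po$edge.length,
       ntip = length(po$tip.label), root = po$edge[nrow(po$edge), 1L])
}

# Felsenstein pruning with per-node rescaling.  Returns lnL, and optionally
# the scaled down-pass partials F and per-child-edge messages D (for ASR).
# Hot path: scalar arithmetic on two partial vectors, closed-form P(t).
mk_prune <- function(td, tipL, q01, q10, root_prior, keep_partials = FALSE) {
  nn <- td$ntip + td$tree$Nnode
  l0 <- rep(1, nn); l1 <- rep(1, nn)
  l0[seq_len(td$ntip)] <- tipL[, 1L]
  l1[seq_len(td$ntip)] <- tipL[, 2L]
  logscale <- 0
  d0 <- d1 <- if (keep_partials) rep(NA_real_, nn) else NULL
  edge <- td$edge; len <- td$len
  ne <- nrow(edge)
  s <- q01 + q10
  if (s > 0) { ev <- exp(-s * len); pi0 <- q10 / s; pi1 <- q01 / s }
  else { ev <- rep(1, ne); pi0 <- 0.5; pi1 <- 0.5 }
  for (i in seq_len(ne)) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    e <- ev[i]
    P00 <- pi0 + pi1 * e; P10 <- pi0 * (1 - e)
    a <- P00 * l0[ch] + (1 - P00) * l1[ch]
    b <- P10 * l0[ch] + (1 - P10) * l1[ch]
    if (keep_partials) { d0[ch] <- a; d1[ch] <- b }
    x <- l0[p] * a; y <- l1[p] * b
    if (x < 1e-100 && y < 1e-100) {   # rescale lazily; exactness unaffected
      m <- max(x, y)
      if (m == 0)
        return(list(lnL = -Inf, F = cbind(l0, l1),
                    D = if (keep_partials) cbind(d0, d1) else NULL,
                    logscale = logscale))
      x <- x / m; y <- y / m
      logscale <- logscale + log(m)
    }
    l0[p] <- x; l1[p] <- y
  }
  lik <- root_prior[1L] * l0[td$root] + root_prior[2L] * l1[td$root]
  lnL <- if (lik > 0) log(lik) + logscale else -Inf
  list(lnL = lnL, F = cbind(l0, l1),
       D = if (keep_partials) cbind(d0, d1) else NULL,
       logscale = logscale)
}

#' Log-likelihood of a binary trait on a tree under an Mk model
#'
#' Felsenstein pruning over the (possibly multifurcating) tree.  Observed
#' tips contribute an indicator partial; tips recorded as `"unknown"` or
#' `"both"` contribute equal likelihood for the two states, and are
#' therefore likelihood-neutral.  The root partial is combined with
#' `root_prior` (default equal, `c(0.5, 0.5)`).
#'
#' @param tree rooted `phylo` with branch lengths (zero lengths allowed).
#' @param traits named vector or [code_traits()] table; see Details.
#' @param model a [rate_model()].
#' @param root_prior length-2 prior over states at the root; need not be
#'   normalized internally (it is validated to sum to 1).
#' @return natural-log likelihood; `-Inf` (with a warning) when the data are
#'   impossible under the model.
#' @export
mk_loglik <- function(tree, traits, model, root_prior = c(0.5, 0.5)) {
  stopifnot(inherits(model, "ppy_rate_model"))
  if (length(root_prior) != 2L || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8)
    stop("`root_prior` must be two non-negative numbers summing to 1")
  td <- mk_tree_data(tree)
  tipL <- tip_partials(traits, td$tree$tip.label)
  res <- mk_prune(td, tipL, model$q01, model$q10, root_prior)
  if (!is.finite(res$lnL))
    warning("zero likelihood: data impossible under this model")
  res$lnL
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param lnL log-likelihood.
#' @param K number of free parameters.
#' @param n sample size (number of tips by convention here).
#' @export
aicc <- function(lnL, K, n) {
  if (n <= K + 1) stop("AICc undefined: need n > K + 1")
  -2 * lnL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit a two-state Mk model by maximum likelihood
#'
#' Rates are estimated by bounded quasi-Newton optimization on the log
#' scale (bounds `[1e-9, 100]` transitions per unit branch length), with
#' `n_starts` deterministic multi-starts on a log-spaced grid and
#' convergence tolerance ~1e-10 in lnL.  AICc uses `n` = number of tips.
#'
#' @inheritParams mk_loglik
#' @param kind `"ER"` (1 parameter) or `"ARD"` (2 parameters).
#' @param bounds rate bounds, default `c(1e-9, 100)`.
#' @param n_starts number of deterministic starting points (default 5).
#' @return `ppy_mkfit`: the fitted [rate_model()], `lnL`, `K`, `n`, `AICc`,
#'   optimizer diagnostics, and `degenerate` flag (fewer than two distinct
#'   observed states).
#' @export
fit_mk <- function(tree, traits, kind = c("ER", "ARD"),
                   root_prior = c(0.5, 0.5), bounds = c(1e-9, 100),
                   n_starts = 5L) {
  kind <- match.arg(kind)
  td <- mk_tree_data(tree)
  tipL <- tip_partials(traits, td$tree$tip.label)
  observed <- unique(apply(tipL, 1L, paste, collapse = ""))
  degenerate <- length(setdiff(observed, "11")) < 2L
  lb <- log(bounds[1L]); ub <- log(bounds[2L])
  npar <- if (kind == "ER") 1L else 2L
  nll <- function(lpar) {
    q <- exp(lpar)
    r <- if (npar == 1L) mk_prune(td, tipL, q, q, root_prior)
         else mk_prune(td, tipL, q[1L], q[2L], root_prior)
    if (!is.finite(r$lnL)) return(1e300)
    -r$lnL
  }
  grid <- seq(log(1e-3), log(10), length.out = n_starts)
  starts <- if (npar == 1L) as.list(grid)
            else lapply(seq_len(n_starts), function(i) c(grid[i], rev(grid)[i]))
  best <- NULL; diags <- list()
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(factr = 10)),
      error = function(e) NULL)
    if (is.null(o)) next
    diags[[length(diags) + 1L]] <- list(start = exp(unlist(s)),
                                        value = -o$value,
                                        convergence = o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("Mk optimization failed from every start")
  q <- exp(best$par)
  model <- if (kind == "ER") rate_model("ER", q = q)
           else rate_model("ARD", q01 = q[1L], q10 = q[2L])
  n <- td$ntip
  lnL <- -best$value
  structure(list(model = model, lnL = lnL, K = model$K, n = n,
                 AICc = aicc(lnL, model$K, n),
                 convergence = best$convergence, starts = diags,
                 degenerate = degenerate, root_prior = root_prior),
            class = "ppy_mkfit")
}

#' @export
print.ppy_mkfit <- function(x, ...) {
  cat(sprintf("Mk fit (%s): lnL = %.6f, K = %d, n = %d, AICc = %.5f\n",
              x$model$kind, x$lnL, x$K, x$n, x$AICc))
  if (x$model$kind == "ER") cat(sprintf("  q = %.6g\n", x$model$q01))
  else cat(sprintf("  q01 = %.6g, q10 = %.6g\n", x$model$q01, x$model$q10))
  invisible(x)
}

#' Select among fitted Mk models by AICc
#'
#' Lowest AICc wins; exact ties go to the earliest fit in the input order
#' (conventionally ER is listed before ARD).  A delta-AICc table is
#' attached as attribute `"delta_table"`.
#'
#' @param fits list of [fit_mk()] results.
#' @return the chosen `ppy_mkfit`.
#' @export
model_select <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  if (inherits(fits, "ppy_mkfit")) return(fits)
  aiccs <- vapply(fits, function(f) f$AICc, numeric(1))
  tab <- data.frame(
    kind = vapply(fits, function(f) f$model$kind, character(1)),
    lnL = vapply(fits, function(f) f$lnL, numeric(1)),
    K = vapply(fits, function(f) f$K, integer(1)),
    AICc = aiccs, dAICc = aiccs - min(aiccs))
  chosen <- fits[[which.min(aiccs)]]   # which.min takes the first on ties
  attr(chosen, "delta_table") <- tab
  chosen
}

#' Marginal ancestral state reconstruction ("scaled likelihoods")
#'
#' For every internal node, the marginal probability of each state given
#' all tip data, computed by a down-pass/up-pass combination.  Vectors are
#' normalized to sum to 1; they equal the likelihood with the node's state
#' fixed to each value in turn, rescaled by the total.
#'
#' @inheritParams mk_loglik
#' @param fit a converged [fit_mk()] (its `root_prior` is reused unless
#'   `root_prior` is given).
#' @param sig_threshold log-likelihood difference for [significance_call()]
#'   flags, default 2.
#' @return `ppy_asr`: data frame with one row per internal node (`node`
#'   number, `label` if present, `p0`, `p1`, `significant`, `direction`)
#'   and attribute `"lnL"`.
#' @export
marginal_asr <- function(tree, traits, fit, root_prior = NULL,
                         sig_threshold = 2) {
  stopifnot(inherits(fit, "ppy_mkfit"))
  if (is.null(root_prior)) root_prior <- fit$root_prior
  td <- mk_tree_data(tree)
  tipL <- tip_partials(traits, td$tree$tip.label)
  q01 <- fit$model$q01; q10 <- fit$model$q10
  down <- mk_prune(td, tipL, q01, q10, root_prior, keep_partials = TRUE)
  if (!is.finite(down$lnL)) stop("zero likelihood; cannot reconstruct")
  edge <- td$edge; len <- td$len
  ntip <- td$ntip; nn <- ntip + td$tree$Nnode
  # children-of lists from the postorder edge matrix
  kids <- vector("list", nn)
  for (i in seq_len(nrow(edge)))
    kids[[edge[i, 1L]]] <- c(kids[[edge[i, 1L]]], i)
  G <- matrix(NA_real_, nn, 2L)
  G[td$root, ] <- root_prior
  # preorder = reverse postorder: parents before children
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    H <- G[p, ]
    for (j in kids[[p]]) {
      sib <- edge[j, 2L]
      if (sib != ch) H <- H * down$D[sib, ]
    }
    P <- mk_pmat(q01, q10, len[i])
    G[ch, ] <- c(H[1L] * P[1L, 1L] + H[2L] * P[2L, 1L],
                 H[1L] * P[1L, 2L] + H[2L] * P[2L, 2L])
    m <- max(G[ch, ])
    if (m > 0) G[ch, ] <- G[ch, ] / m   # scale freely; normalized below
  }
  nodes <- (ntip + 1L):nn
  w <- down$F[nodes, , drop = FALSE] * G[nodes, , drop = FALSE]
  pm <- w / rowSums(w)
  sig <- t(vapply(seq_len(nrow(pm)), function(i) {
    s <- significance_call(pm[i, ], threshold = sig_threshold)
    c(s$significant, s$direction)
  }, numeric(2)))
  labs <- if (!is.null(td$tree$node.label)) td$tree$node.label
          else rep(NA_character_, length(nodes))
  out <- data.frame(node = nodes, label = labs,
                    p0 = pm[, 1L], p1 = pm[, 2L],
                    significant = as.logical(sig[, 1L]),
                    direction = as.integer(sig[, 2L]),
                    stringsAsFactors = FALSE)
  # report in the node numbering of the input tree: map postorder-tree node
  # numbers back (reorder.phylo preserves node numbering, only edge order
  # changes, so numbers already match the input tree)
  attr(out, "lnL") <- down$lnL
  attr(out, "model") <- fit$model
  class(out) <- c("ppy_asr", "data.frame")
  out
}

#' Proportional-likelihood significance call for a node
#'
#' A node's reconstruction is called significant when the log difference
#' between the two scaled likelihoods is at least `threshold` (rule of
#' thumb: 2).
#'
#' @param p numeric length-2 scaled-likelihood vector, summing to 1.
#' @param threshold log-likelihood difference required, default 2.
#' @return list with `significant` (logical), `direction` (0 or 1, the
#'   argmax state) and `delta` (the absolute log difference).
#' @export
significance_call <- function(p, threshold = 2) {
  if (length(p) != 2L || any(!is.finite(p)) || any(p < 0))
    stop("`p` must be two non-negative finite numbers")
  # printed scaled likelihoods are rounded, so allow slack and normalize
  # (the log difference is invariant under rescaling)
  if (abs(sum(p) - 1) > 0.01) stop("`p` must sum to 1")
  p <- p / sum(p)
  eps <- 1e-16
  if (any(p < eps)) {
    warning("zero entry in scaled-likelihood vector; clamped to 1e-16")
    p <- pmax(p, eps)
  }
  delta <- abs(log(p[1L]) - log(p[2L]))
  list(significant = delta >= threshold,
       direction = as.integer(which.max(p) - 1L), delta = delta)
}

#' Code tip traits from species-level records
#'
#' Builds the trait table used by the Mk machinery from per-species
#' developmental-mode records.  At genus level a tip is coded `"both"` when
#' congeners include both modes (or any congener is itself recorded as
#' both), by the single known mode when only one is recorded in the genus,
#' and `"unknown"` when nothing is known at that level.  Per-tip overrides
#' (e.g. family-level coding for an undescribed species) are applied last.
#'
#' @param records data frame with columns `species`, `genus`, `mode`
#'   (values among `"indirect"`, `"direct"`, `"both"`, `"unknown"` or `NA`).
#' @param level `"genus"` (default) or `"species"`.
#' @param overrides optional named character vector, tip -> observation.
#' @param tips optional character vector of tree tips that must all be
#'   covered (error listing any tip without a record).
#' @return `ppy_traits` data frame with columns `tip`, `observation`;
#'   state indexing (0 = indirect, 1 = direct) is recorded as attributes.
#' @export
code_traits <- function(records, level = c("genus", "species"),
                        overrides = NULL, tips = NULL) {
  level <- match.arg(level)
  stopifnot(all(c("species", "genus", "mode") %in% names(records)))
  ok <- c("indirect", "direct", "both", "unknown")
  mode <- as.character(records$mode)
  mode[is.na(mode)] <- "unknown"
  if (!all(mode %in% ok))
    stop("modes must be among: ", paste(ok, collapse = ", "))
  if (!is.null(tips)) {
    absent <- setdiff(tips, records$species)
    absent <- setdiff(absent, names(overrides))
    if (length(absent))
      stop("tips without a record: ", paste(absent, collapse = ", "))
  }
  obs <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (level == "species") {
      obs[i] <- mode[i]
    } else {
      congeners <- mode[records$genus == records$genus[i]]
      known <- setdiff(unique(congeners), "unknown")
      obs[i] <- if ("both" %in% known ||
                    all(c("indirect", "direct") %in% known)) "both"
                else if (length(known) == 1L) known
                else "unknown"
    }
  }
  out <- data.frame(tip = records$species, observation = obs,
                    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    if (!all(overrides %in% ok)) stop("override values must be valid modes")
    for (tp in names(overrides)) {
      if (tp %in% out$tip) out$observation[out$tip == tp] <- overrides[[tp]]
      else out <- rbind(out, data.frame(tip = tp,
                                        observation = overrides[[tp]],
                                        stringsAsFactors = FALSE))
    }
  }
  attr(out, "state0") <- "indirect"
  attr(out, "state1") <- "direct"
  class(out) <- c("ppy_traits", "data.frame")
  out
}
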