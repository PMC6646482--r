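# Linear-chain conditional random field for token sequence labeling.
#
# The model scores a label sequence y for a token sequence with features
# x as  sum_t  w' f(x, t, y_t)  +  sum_t  T[y_{t-1}, y_t],  with emission
# weights w over sparse binary token features and a dense label-transition
# matrix T.  Training maximizes the L2-penalized conditional log-likelihood
# with L-BFGS; gradients come from forward-backward marginals.  Decoding is
# Viterbi.  This is the standard formulation used by CRF toolkits for
# named-entity tagging.

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# feature name prefix ("w[-1]", "dict", "bias", ...) used for template checks
.feat_prefix <- function(f) sub("=.*$", "", f)

.crf_pack <- function(W, Trans) c(as.vector(W), as.vector(Trans))
.crf_unpack <- function(par, nfeat, K) {
  list(W = matrix(par[seq_len(nfeat * K)], nfeat, K),
       Trans = matrix(par[nfeat * K + seq_len(K * K)], K, K))
}

# Emission score matrix (n x K) for one sentence of integer feature ids.
.emissions <- function(fids, W, K) {
  n <- length(fids)
  E <- matrix(0, n, K)
  for (t in seq_len(n)) {
    f <- fids[[t]]
    if (length(f) > 0) E[t, ] <- colSums(W[f, , drop = FALSE])
  }
  E
}

# Penalized negative log-likelihood and gradient over the whole corpus.
.crf_nll_grad <- function(par, xi, yi, nfeat, K, l2) {
  p <- .crf_unpack(par, nfeat, K)
  W <- p$W; Trans <- p$Trans
  gW <- matrix(0, nfeat, K)
  gT <- matrix(0, K, K)
  nll <- 0
  for (s in seq_along(xi)) {
    fids <- xi[[s]]
    y <- yi[[s]]
    n <- length(fids)
    if (n == 0) next
    E <- .emissions(fids, W, K)
    # forward
    logA <- matrix(0, n, K)
    logA[1, ] <- E[1, ]
    if (n > 1) {
      for (t in 2:n) {
        prev <- logA[t - 1, ]
        m <- max(prev)
        logA[t, ] <- E[t, ] + m + log(colSums(exp(prev - m + Trans)))
      }
    }
    logZ <- .logsumexp(logA[n, ])
    # backward
    logB <- matrix(0, n, K)
    if (n > 1) {
      for (t in (n - 1):1) {
        nxt <- logB[t + 1, ] + E[t + 1, ]
        m <- max(nxt)
        logB[t, ] <- m +
          log(rowSums(exp(Trans + matrix(nxt - m, K, K, byrow = TRUE))))
      }
    }
    # observed score
    obs <- sum(E[cbind(seq_len(n), y)])
    if (n > 1) obs <- obs + sum(Trans[cbind(y[-n], y[-1])])
    nll <- nll + (logZ - obs)
    # emission gradient: marginals minus indicators
    D <- exp(logA + logB - logZ)
    D[cbind(seq_len(n), y)] <- D[cbind(seq_len(n), y)] - 1
    for (t in seq_len(n)) {
      f <- fids[[t]]
      if (length(f) > 0) {
        gW[f, ] <- gW[f, ] + matrix(D[t, ], length(f), K, byrow = TRUE)
      }
    }
    # transition gradient: pairwise marginals minus indicators
    if (n > 1) {
      for (t in 2:n) {
        q <- exp(outer(logA[t - 1, ], logB[t, ] + E[t, ], "+") +
                   Trans - logZ)
        gT <- gT + q
        gT[y[t - 1], y[t]] <- gT[y[t - 1], y[t]] - 1
      }
    }
  }
  nll <- nll + l2 * sum(par^2)
  grad <- .crf_pack(gW, gT) + 2 * l2 * par
  list(value = nll, gradient = grad)
}

#' Fit a linear-chain conditional random field
#'
#' Trains a sequence labeler on featurized token sequences with BIO labels.
#' Emission weights over sparse binary features and a dense label-transition
#' matrix are estimated by maximizing the L2-penalized conditional
#' log-likelihood with L-BFGS (the default objective and optimizer of
#' standard CRF toolkits).  The fitted transition matrix is the basis of
#' label-transition analysis, see [extract_transition_scores()].
#'
#' @param x List of feature sequences, one per sentence; each element is a
#'   list of character vectors (token feature sets), as produced by
#'   [featurize()].
#' @param y List of character vectors of BIO labels, aligned with `x`.
#' @param labels Declared label set.  Defaults to the labels observed in
#'   `y`; when supplied, a label in `y` outside this set is an error.
#' @param l2 L2 regularization strength (default 1, the common toolkit
#'   default).
#' @param maxit Maximum L-BFGS iterations.
#' @param verbose Print optimizer progress.
#' @return An object of class `"crf"` with components `W` (emission weight
#'   matrix, features x labels), `transitions` (label x label score
#'   matrix), `labels`, `features`, `template` (feature-name prefixes seen
#'   at training), and `convergence` info.  Methods: [predict.crf()],
#'   [print.crf()], [coef.crf()], [logLik.crf()].
#' @examples
#' toks <- tokenize_and_pos("liver cyst")
#' x <- list(featurize(toks))
#' y <- list(c("B-ANATOMICAL_ENTITY", "B-IMAGING_OBSERVATION"))
#' m <- crf(x, y, maxit = 20)
#' predict(m, x)
#' @export
crf <- function(x, y, labels = NULL, l2 = 1.0, maxit = 100L,
                verbose = FALSE) {
  if (length(x) == 0 || length(y) == 0) {
    stop("empty training corpus", call. = FALSE)
  }
  stopifnot(length(x) == length(y))
  seen <- unique(unlist(y))
  if (is.null(labels)) {
    labels <- union("O", seen)
  } else if (!all(seen %in% labels)) {
    stop("label(s) outside the declared label set: ",
         paste(setdiff(seen, labels), collapse = ", "), call. = FALSE)
  }
  K <- length(labels)
  feats <- unique(unlist(x, recursive = TRUE, use.names = FALSE))
  nfeat <- length(feats)
  fmap <- stats::setNames(seq_len(nfeat), feats)
  xi <- lapply(x, function(sent) {
    lapply(sent, function(tokf) unname(fmap[tokf]))
  })
  yi <- lapply(y, function(lab) {
    idx <- match(lab, labels)
    stopifnot(!anyNA(idx))
    idx
  })
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!identical(cache$par, par)) {
      cache$res <- .crf_nll_grad(par, xi, yi, nfeat, K, l2)
      cache$par <- par
    }
    cache$res
  }
  par0 <- numeric(nfeat * K + K * K)
  opt <- stats::optim(
    par0,
    fn = function(p) evaluate(p)$value,
    gr = function(p) evaluate(p)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = as.integer(maxit),
                   trace = if (verbose) 1L else 0L)
  )
  p <- .crf_unpack(opt$par, nfeat, K)
  dimnames(p$Trans) <- list(from = labels, to = labels)
  rownames(p$W) <- feats
  colnames(p$W) <- labels
  structure(
    list(
      W = p$W,
      transitions = p$Trans,
      labels = labels,
      features = feats,
      template = sort(unique(vapply(feats, .feat_prefix, character(1)))),
      l2 = l2,
      convergence = list(code = opt$convergence, nll = opt$value,
                         counts = opt$counts),
      n_sentences = length(x)
    ),
    class = "crf"
  )
}

#' Predict label sequences with a fitted CRF
#'
#' Viterbi decoding followed by BIO repair, so every returned sequence is
#' BIO-valid.  Features unseen at training time are ignored, but a feature
#' whose *name* (template prefix, e.g. `w[-1]`, `dict`) was never seen
#' signals a template mismatch and raises an error.
#'
#' @param object A `"crf"` model.
#' @param newdata A list of feature sequences (as for [crf()]), or a single
#'   feature sequence (a list of character vectors).
#' @param ... Unused.
#' @return A list of character label vectors (or a single vector when a
#'   single sequence was given).
#' @export
predict.crf <- function(object, newdata, ...) {
  single <- length(newdata) > 0 &&
    all(vapply(newdata, is.character, logical(1)))
  seqs <- if (single) list(newdata) else newdata
  K <- length(object$labels)
  fmap <- stats::setNames(seq_along(object$features), object$features)
  out <- lapply(seqs, function(sent) {
    n <- length(sent)
    if (n == 0) return(character(0))
    prefixes <- unique(vapply(unlist(sent), .feat_prefix, character(1)))
    bad <- setdiff(prefixes, object$template)
    if (length(bad) > 0) {
      stop("feature template mismatch; unknown feature name(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    fids <- lapply(sent, function(tokf) {
      idx <- fmap[tokf]
      unname(idx[!is.na(idx)])
    })
    E <- .emissions(fids, object$W, K)
    delta <- matrix(0, n, K)
    psi <- matrix(0L, n, K)
    delta[1, ] <- E[1, ]
    if (n > 1) {
      for (t in 2:n) {
        M <- delta[t - 1, ] + object$transitions
        delta[t, ] <- E[t, ] + apply(M, 2, max)
        psi[t, ] <- apply(M, 2, which.max)
      }
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    if (n > 1) {
      for (t in (n - 1):1) path[t] <- psi[t + 1L, path[t + 1L]]
    }
    bio_repair(object$labels[path])
  })
  if (single) out[[1]] else out
}

#' @export
print.crf <- function(x, ...) {
  cat("Linear-chain CRF\n")
  cat("  labels:   ", length(x$labels), " (",
      paste(x$labels[seq_len(min(5, length(x$labels)))], collapse = ", "),
      if (length(x$labels) > 5) ", ..." else "", ")\n", sep = "")
  cat("  features: ", length(x$features), "\n", sep = "")
  cat("  trained on ", x$n_sentences, " sentences; penalized NLL ",
      format(x$convergence$nll, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Coefficients of a fitted CRF
#' @param object A `"crf"` model.
#' @param what `"transitions"` for the label-transition score matrix,
#'   `"emissions"` for the feature weight matrix.
#' @param ... Unused.
#' @export
coef.crf <- function(object, what = c("transitions", "emissions"), ...) {
  switch(match.arg(what),
         transitions = object$transitions,
         emissions = object$W)
}

#' @export
logLik.crf <- function(object, ...) {
  structure(-object$convergence$nll,
            df = length(object$W) + length(object$transitions),
            class = "logLik")
}

#' Label-transition scores of a fitted CRF
#'
#' Returns the learned label-to-label transition parameters, the quantity
#' used to explore which descriptor types tend to follow which (for
#' example, whether a measurement is most often followed by an imaging
#' observation or an anatomical entity).  Linear-chain CRF transition
#' parameters are unnormalized scores; a softmax-normalized view (rows sum
#' to one) is available for readers who prefer a conditional-probability
#' scale, and is labeled as such in the attribute `scale`.
#'
#' @param model A fitted `"crf"` model.
#' @param normalize `"none"` (raw scores, default) or `"softmax"`
#'   (row-normalized).
#' @return A label x label numeric matrix with attribute `scale`.
#' @export
extract_transition_scores <- function(model,
                                      normalize = c("none", "softmax")) {
  if (!inherits(model, "crf")) {
    stop("not a trained crf model", call. = FALSE)
  }
  normalize <- match.arg(normalize)
  Tm <- model$transitions
  if (normalize == "softmax") {
    Tm <- t(apply(Tm, 1, function(r) {
      e <- exp(r - max(r)); e / sum(e)
    }))
    dimnames(Tm) <- dimnames(model$transitions)
  }
  attr(Tm, "scale") <- if (normalize == "none") "raw score" else "softmax"
  Tm
}

#' Save / load a fitted CRF
#'
#' Serialization keeps the full parameter set, label set and feature
#' template, so a reloaded model gives bit-identical predictions.
#'
#' @param model A `"crf"` model.
#' @param path File path.
#' @return `crf_save` returns `path` invisibly; `crf_load` returns the
#'   model.
#' @export
crf_save <- function(model, path) {
  stopifnot(inherits(model, "crf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname crf_save
#' @export
crf_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "crf")) {
    stop("file does not contain a crf model: ", path, call. = FALSE)
  }
  model
}
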