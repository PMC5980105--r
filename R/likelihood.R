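# SECR likelihood: model parsing, data preparation, and evaluation.
#
# The full likelihood for n detected animals with histories omega_i is
#   log L = sum_i log[ (a/1000) sum_m D(x_m) Pr(omega_i | x_m) ]
#           - (a/1000) sum_m D(x_m) pdot(x_m) - log(n!)
# where the mask sum approximates the integral over activity-center space,
# a is the mask cell area (km^2) and D is in bears per 1000 km^2.
# Detection is Bernoulli half-normal per animal x detector x occasion.

DET_SPECIALS <- c("trend", "b", "bk", "h2")

parse_par_formula <- function(f, par, layout, S) {
  tt <- stats::terms(f)
  if (attr(tt, "response") != 0) stop("detection formulas must be one-sided")
  labs <- attr(tt, "term.labels")
  if (any(grepl(":", labs, fixed = TRUE)))
    stop("interactions are not supported in detection models")
  covs <- setdiff(labs, DET_SPECIALS)
  bad <- setdiff(covs, names(layout))
  if (length(bad))
    stop("unknown detection covariate(s): ", paste(bad, collapse = ", "))
  X <- matrix(1, nrow(layout), 1L)
  cn <- par
  if ("trend" %in% labs) {
    X <- cbind(X, layout$occasion - (S + 1) / 2)
    cn <- c(cn, paste0(par, ".trend"))
  }
  for (cv in covs) {
    v <- layout[[cv]]
    if (!all(is.finite(v))) stop("non-finite values in covariate ", cv)
    sdv <- stats::sd(v)
    if (sdv == 0) stop("covariate ", cv, " is constant over detectors")
    X <- cbind(X, (v - mean(v)) / sdv)
    cn <- c(cn, paste0(par, ".", cv))
  }
  colnames(X) <- cn
  list(X = X,
       has_b = "b" %in% labs, has_bk = "bk" %in% labs,
       has_h2 = "h2" %in% labs, covs = covs)
}

# Standardized (z-scored over in-grid mask points) density design matrix.
density_design <- function(density, mask) {
  vars <- all.vars(density)
  bad <- setdiff(vars, names(mask))
  if (length(bad))
    stop("unknown density covariate(s): ", paste(bad, collapse = ", "))
  ref <- if (!is.null(mask$inside_grid) && any(mask$inside_grid))
    mask$inside_grid else rep(TRUE, nrow(mask))
  dat <- data.frame(row.names = seq_len(nrow(mask)))
  centers <- scales <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    centers[v] <- mean(mask[[v]][ref])
    scales[v] <- stats::sd(mask[[v]][ref])
    if (!is.finite(scales[v]) || scales[v] == 0)
      stop("density covariate ", v, " is constant over the in-grid mask")
    dat[[v]] <- (mask[[v]] - centers[v]) / scales[v]
  }
  Xd <- stats::model.matrix(density, data = dat)
  colnames(Xd) <- ifelse(colnames(Xd) == "(Intercept)", "D",
                         paste0("D.", colnames(Xd)))
  list(Xd = Xd, centers = centers, scales = scales, formula = density)
}

validate_captures <- function(capture, layout, S) {
  req <- c("animal_id", "occasion", "detector_id")
  miss <- setdiff(req, names(capture))
  if (length(miss)) stop("capture data lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(capture)) {
    bad <- which(capture$occasion < 1 | capture$occasion > S)
    if (length(bad)) stop("capture row ", bad[1L], ": occasion ",
                          capture$occasion[bad[1L]], " outside 1..", S)
    key <- paste(capture$occasion, capture$detector_id)
    lkey <- paste(layout$occasion, layout$detector_id)
    k <- match(key, lkey)
    if (anyNA(k)) {
      bad <- which(is.na(k))[1L]
      stop("capture row ", bad, ": detector '", capture$detector_id[bad],
           "' not in layout for occasion ", capture$occasion[bad])
    }
    if (anyDuplicated(paste(capture$animal_id, key)))
      stop("duplicate (animal, occasion, detector) capture record")
    return(k)
  }
  integer(0)
}

# Precompute everything the likelihood needs that does not depend on theta.
secr_prep <- function(capture, layout, mask,
                      model = list(g0 = ~1, sigma = ~1), density = ~1) {
  S <- layout_occasions(layout)
  k_all <- validate_captures(capture, layout, S)
  d2 <- dist2_cpp(layout$x, layout$y, mask$x, mask$y)
  animals <- sort(unique(as.character(capture$animal_id)))
  n <- length(animals)
  aidx <- match(as.character(capture$animal_id), animals)
  detcols <- sort(unique(k_all))
  j_all <- match(k_all, detcols)
  f_animal <- rep(NA_integer_, n)
  if (n) f_animal <- as.integer(tapply(capture$occasion, aidx, min)[as.character(seq_len(n))])
  g0i <- parse_par_formula(model$g0 %||% ~1, "g0", layout, S)
  sgi <- parse_par_formula(model$sigma %||% ~1, "sigma", layout, S)
  has_b <- g0i$has_b || sgi$has_b
  has_bk <- g0i$has_bk || sgi$has_bk
  any_h2 <- g0i$has_h2 || sgi$has_h2

  bk_entries <- NULL
  if (has_bk && nrow(capture)) {
    # site-specific experience: offsets apply at a site from the occasion
    # after the animal's first detection there
    first_site <- stats::aggregate(
      occasion ~ animal_id + detector_id, data = capture, FUN = min)
    ent <- list()
    for (r in seq_len(nrow(first_site))) {
      rows <- which(layout$detector_id == first_site$detector_id[r] &
                      layout$occasion > first_site$occasion[r])
      if (!length(rows)) next
      ai <- match(as.character(first_site$animal_id[r]), animals)
      det_key <- paste(capture$occasion[aidx == ai],
                       capture$detector_id[aidx == ai])
      ent[[length(ent) + 1L]] <- data.frame(
        a = ai, k = rows, s = layout$occasion[rows],
        detected = paste(layout$occasion[rows],
                         layout$detector_id[rows]) %in% det_key)
    }
    if (length(ent)) bk_entries <- do.call(rbind, ent)
  }

  dens <- density_design(density, mask)
  par_names <- c(colnames(g0i$X),
                 if (g0i$has_b) "g0.b", if (g0i$has_bk) "g0.bk",
                 if (g0i$has_h2) "g0.h2",
                 colnames(sgi$X),
                 if (sgi$has_b) "sigma.b", if (sgi$has_bk) "sigma.bk",
                 if (sgi$has_h2) "sigma.h2",
                 if (any_h2) "pmix",
                 colnames(dens$Xd))
  structure(list(
    layout = layout, mask = mask, capture = capture,
    S = S, K = nrow(layout), M = nrow(mask), n = n,
    animals = animals, aidx = aidx, occ = as.integer(layout$occasion),
    d2 = d2, cell_area = mask_cell_area(mask),
    detcols = detcols, k_all = k_all, j_all = j_all,
    s_all = as.integer(capture$occasion), f_animal = f_animal,
    g0i = g0i, sgi = sgi, has_b = has_b, has_bk = has_bk, any_h2 = any_h2,
    bk_entries = bk_entries, dens = dens, par_names = par_names,
    cache = new.env(parent = emptyenv())
  ), class = "secr_prep")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_theta <- function(theta, prep) {
  nm <- prep$par_names
  if (length(theta) != length(nm))
    stop("theta has length ", length(theta), ", expected ", length(nm))
  names(theta) <- nm
  pick <- function(keys) unname(theta[keys])
  g0X <- colnames(prep$g0i$X); sgX <- colnames(prep$sgi$X)
  list(beta_g0 = pick(g0X),
       g0_b = if (prep$g0i$has_b) theta[["g0.b"]] else 0,
       g0_bk = if (prep$g0i$has_bk) theta[["g0.bk"]] else 0,
       g0_h2 = if (prep$g0i$has_h2) theta[["g0.h2"]] else 0,
       beta_sigma = pick(sgX),
       sigma_b = if (prep$sgi$has_b) theta[["sigma.b"]] else 0,
       sigma_bk = if (prep$sgi$has_bk) theta[["sigma.bk"]] else 0,
       sigma_h2 = if (prep$sgi$has_h2) theta[["sigma.h2"]] else 0,
       pmix_l = if (prep$any_h2) theta[["pmix"]] else NULL,
       betaD = unname(theta[colnames(prep$dens$Xd)]))
}

# Detection-parameter stage: everything that depends on (g0, sigma) betas.
# Cached on the detection subvector so density-model optimization steps that
# leave detection parameters unchanged are nearly free.
secr_stage1 <- function(prep, pars) {
  key <- c(pars$beta_g0, pars$g0_b, pars$g0_bk, pars$g0_h2,
           pars$beta_sigma, pars$sigma_b, pars$sigma_bk, pars$sigma_h2)
  if (!is.null(prep$cache$key) && length(prep$cache$key) == length(key) &&
      all(prep$cache$key == key))
    return(prep$cache$val)
  eta_g0 <- drop(prep$g0i$X %*% pars$beta_g0)
  eta_sg <- drop(prep$sgi$X %*% pars$beta_sigma)
  if (!all(is.finite(eta_g0)) || !all(is.finite(eta_sg)))
    stop("non-finite detection linear predictor")
  C <- if (prep$any_h2) 2L else 1L
  E <- if (prep$has_b) 2L else 1L
  n <- prep$n; M <- prep$M; S <- prep$S
  classes <- vector("list", C)
  for (cc in seq_len(C)) {
    kern <- vector("list", E)
    for (e in seq_len(E)) {
      g0v <- stats::plogis(eta_g0 + (cc == 2L) * pars$g0_h2 +
                             (e == 2L) * pars$g0_b)
      sgv <- exp(eta_sg + (cc == 2L) * pars$sigma_h2 +
                   (e == 2L) * pars$sigma_b)
      kern[[e]] <- secr_kernel_cpp(prep$d2, g0v, 1 / (2 * sgv^2),
                                   prep$occ, S, prep$detcols)
    }
    totQ <- colSums(kern[[1L]]$logQ)
    pdotc <- 1 - exp(totQ)
    if (prep$has_b) {
      cumN <- apply(kern[[1L]]$logQ, 2L, cumsum)          # S x M
      sufE <- apply(kern[[2L]]$logQ[S:1, , drop = FALSE], 2L, cumsum)[S:1, , drop = FALSE]
      struct <- matrix(0, n, M)
      for (f in unique(prep$f_animal)) {
        rows <- prep$f_animal == f
        v <- cumN[f, ] + if (f < S) sufE[f + 1L, ] else 0
        struct[rows, ] <- matrix(v, sum(rows), M, byrow = TRUE)
      }
    } else {
      struct <- NULL                                       # use totQ broadcast
    }
    # detection terms: log p - log(1-p) at each animal's detected columns
    DT <- matrix(0, n, M)
    if (length(prep$j_all)) {
      Wn <- kern[[1L]]$LP - kern[[1L]]$L1P
      Wall <- Wn[prep$j_all, , drop = FALSE]
      if (prep$has_b) {
        We <- kern[[2L]]$LP - kern[[2L]]$L1P
        late <- prep$s_all > prep$f_animal[prep$aidx]
        if (any(late)) Wall[late, ] <- We[prep$j_all[late], , drop = FALSE]
      }
      DT <- rowsum(Wall, group = prep$aidx, reorder = TRUE)
    }
    # site-specific behavioural (bk) corrections, computed per column in R
    if (!is.null(prep$bk_entries)) {
      be <- prep$bk_entries
      for (r in seq_len(nrow(be))) {
        k <- be$k[r]; a <- be$a[r]
        e <- if (prep$has_b && be$s[r] > prep$f_animal[a]) 2L else 1L
        off_b_g0 <- (e == 2L) * pars$g0_b
        off_b_sg <- (e == 2L) * pars$sigma_b
        g0b <- stats::plogis(eta_g0[k] + (cc == 2L) * pars$g0_h2 + off_b_g0)
        sgb <- exp(eta_sg[k] + (cc == 2L) * pars$sigma_h2 + off_b_sg)
        g0c <- stats::plogis(eta_g0[k] + (cc == 2L) * pars$g0_h2 + off_b_g0 +
                               pars$g0_bk)
        sgc <- exp(eta_sg[k] + (cc == 2L) * pars$sigma_h2 + off_b_sg +
                     pars$sigma_bk)
        pb <- pmin(g0b * exp(-prep$d2[k, ] / (2 * sgb^2)), 1 - 1e-12)
        pc <- pmin(g0c * exp(-prep$d2[k, ] / (2 * sgc^2)), 1 - 1e-12)
        DT[a, ] <- DT[a, ] + if (be$detected[r])
          log(pmax(pc, 1e-300)) - log(pmax(pb, 1e-300))
        else log1p(-pc) - log1p(-pb)
      }
    }
    classes[[cc]] <- list(totQ = totQ, struct = struct, DT = DT, pdot = pdotc)
  }
  val <- list(classes = classes, C = C)
  prep$cache$key <- key
  prep$cache$val <- val
  val
}

logsumexp_rows <- function(A) {
  rm <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  rm + log(rowSums(exp(A - rm)))
}

# Density stage. Returns the log-likelihood; when concentrate = TRUE the
# density intercept in betaD is replaced by its closed-form conditional MLE
# (the intercept profiles out of the inhomogeneous-Poisson likelihood).
secr_stage2 <- function(prep, st1, pars, concentrate = FALSE) {
  Xd <- prep$dens$Xd
  betaD <- pars$betaD
  r <- if (ncol(Xd) > 1L)
    drop(Xd[, -1L, drop = FALSE] %*% betaD[-1L]) else rep(0, prep$M)
  if (any(abs(r) > 50)) stop("density linear predictor overflows at mask point ",
                             which.max(abs(r)))
  pi1 <- if (st1$C == 2L) stats::plogis(pars$pmix_l) else 1
  w <- if (st1$C == 2L) c(pi1, 1 - pi1) else 1
  pdot_mix <- Reduce(`+`, Map(function(cl, wt) wt * cl$pdot, st1$classes,
                              as.list(w)))
  aa <- prep$cell_area / 1000
  G <- aa * sum(exp(r) * pdot_mix)
  n <- prep$n
  b0 <- if (concentrate) {
    if (n == 0L) stop("cannot concentrate the density intercept with no detections")
    log(n / G)
  } else betaD[1L]
  if (n == 0L)
    return(list(loglik = -exp(b0) * G, b0 = b0))
  Alist <- vector("list", st1$C)
  for (cc in seq_len(st1$C)) {
    cl <- st1$classes[[cc]]
    A <- cl$DT
    A <- if (is.null(cl$struct))
      sweep(A, 2L, cl$totQ + r, "+") else A + cl$struct + rep(r, each = n)
    Alist[[cc]] <- A + log(w[cc])
  }
  A <- do.call(cbind, Alist)
  Li <- logsumexp_rows(A)                 # excludes b0 and log(a/1000)
  ll <- sum(Li) + n * (b0 + log(aa)) - exp(b0) * G - lgamma(n + 1)
  list(loglik = ll, b0 = b0, Li = Li, G = G)
}

# Dispatching evaluator: a single-pass C++ path for the common model class
# (covariate / trend models without behavioural response or mixture), and
# the staged R path for b / bk / h2 models. Both use identical numerics.
secr_eval <- function(prep, pars, concentrate = FALSE) {
  fast <- !prep$has_b && !prep$has_bk && !prep$any_h2
  if (!fast) {
    st1 <- secr_stage1(prep, pars)
    return(secr_stage2(prep, st1, pars, concentrate))
  }
  Xd <- prep$dens$Xd
  r <- if (ncol(Xd) > 1L)
    drop(Xd[, -1L, drop = FALSE] %*% pars$betaD[-1L]) else rep(0, prep$M)
  if (any(abs(r) > 50))
    stop("density linear predictor overflows at mask point ",
         which.max(abs(r)))
  eta_g0 <- drop(prep$g0i$X %*% pars$beta_g0)
  eta_sg <- drop(prep$sgi$X %*% pars$beta_sigma)
  if (!all(is.finite(eta_g0)) || !all(is.finite(eta_sg)))
    stop("non-finite detection linear predictor")
  fc <- secr_fast_cpp(prep$d2, stats::plogis(eta_g0),
                      1 / (2 * exp(2 * eta_sg)),
                      prep$k_all, prep$aidx, prep$n, r)
  aa <- prep$cell_area / 1000
  G <- aa * fc$G
  n <- prep$n
  b0 <- if (concentrate) {
    if (n == 0L) stop("cannot concentrate the density intercept with no detections")
    log(n / G)
  } else pars$betaD[1L]
  if (n == 0L) return(list(loglik = -exp(b0) * G, b0 = b0))
  ll <- sum(fc$Li) + n * (b0 + log(aa)) - exp(b0) * G - lgamma(n + 1)
  list(loglik = ll, b0 = b0, Li = fc$Li, G = G)
}

#' SECR log-likelihood
#'
#' Full log-likelihood of the spatially explicit capture-recapture model at
#' a given parameter vector: half-normal Bernoulli detection with optional
#' occasion trend, site covariates, behavioural responses (`b`, `bk`) and a
#' 2-class finite mixture (`h2`), and a log-linear density surface over the
#' habitat mask. Includes the `-log(n!)` constant so values are comparable
#' across models fitted to the same data.
#'
#' @param capture Capture data (`animal_id`, `occasion`, `detector_id`).
#' @param layout Detector layout for all occasions.
#' @param mask Habitat mask from [make_mask()].
#' @param theta Parameter vector on link scales, ordered as reported by
#'   [secr_par_names()]: detection betas (logit g0, log sigma), optional
#'   `pmix` (logit of class-1 weight), then density betas (log bears per
#'   1000 km^2).
#' @param model List of one-sided formulas for `g0` and `sigma`; terms may
#'   include `trend`, `b`, `bk`, `h2` and layout covariate names.
#' @param density One-sided formula over mask covariates (e.g. `~ RSF`).
#' @return The log-likelihood (scalar).
#' @export
secr_loglik <- function(capture, layout, mask, theta,
                        model = list(g0 = ~1, sigma = ~1), density = ~1) {
  prep <- secr_prep(capture, layout, mask, model, density)
  pars <- split_theta(theta, prep)
  secr_eval(prep, pars)$loglik
}

#' Parameter names for a SECR model specification
#'
#' @inheritParams secr_loglik
#' @return Character vector naming the packed parameter vector.
#' @export
secr_par_names <- function(capture, layout, mask,
                           model = list(g0 = ~1, sigma = ~1), density = ~1) {
  secr_prep(capture, layout, mask, model, density)$par_names
}
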