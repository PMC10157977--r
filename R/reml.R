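# Repeated-records animal model:
#   y = X b + Z a + Z pe + e,  a ~ N(0, G sa2), pe ~ N(0, I spe2),
#   e ~ N(0, I se2)
# fitted by average-information REML with EM fallback. All heavy algebra is
# reduced to bull-level (q x q) matrices through the Woodbury identity
#   V^-1 = (I - Z (se2 H^-1 + Z'Z)^-1 Z') / se2,  H = sa2 G + spe2 I,
# so cost per iteration is O(n p + q^2 p + q^3) rather than O(n^3).

.vcNames <- c("sigma_a2", "sigma_pe2", "sigma_e2")

# design matrix for the fixed part of models (1)-(3); factor levels are
# string-sorted, first level is the reference. Single-level factors are
# absorbed by the intercept.
.buildDesign <- function(ph, covariates = NULL, includeAge = TRUE) {
  n <- nrow(ph)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (f in c("year_season", "center", "interval", "n_sample")) {
    v <- factor(as.character(ph[[f]]),
                levels = sort(unique(as.character(ph[[f]]))))
    if (nlevels(v) < 2) next
    mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
    colnames(mm) <- paste0(f, levels(v)[-1])
    X <- cbind(X, mm)
  }
  if (includeAge && "age_months" %in% names(ph))
    X <- cbind(X, age_months = as.numeric(ph$age_months))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("f", seq_len(ncol(covariates)))
    idx <- match(as.character(ph$bull_id), rownames(covariates))
    if (anyNA(idx))
      stop("bull(s) missing from the covariate table: ",
           paste(utils::head(unique(ph$bull_id[is.na(idx)])), collapse = ", "))
    X <- cbind(X, covariates[idx, , drop = FALSE])
  }
  X
}

# drop aliased columns via pivoted QR; returns reduced X and bookkeeping
.reduceRank <- function(X) {
  qrX <- qr(X)
  rank <- qrX$rank
  keep <- sort(qrX$pivot[seq_len(rank)])
  if (rank < ncol(X))
    warning("collinear fixed-effect column(s) reported as NA: ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)],
                  collapse = ", "))
  list(X = X[, keep, drop = FALSE], keep = keep, rank = rank,
       names = colnames(X))
}

# core AI-REML engine at bull level; returns estimates and the projections
# needed by the scan. bi: record -> bull index; G aligned to bull levels.
.airemlFit <- function(y, X, bi, q, G, start, maxIter = 200L,
                       tolVc = 1e-8, tolLl = 1e-9) {
  n <- length(y)
  p <- ncol(X)
  D <- tabulate(bi, nbins = q)
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors; lam <- pmax(eg$values, 0)
  vp <- var(y)
  flo <- 1e-10 * vp
  th <- pmax(start, flo)

  eval_at <- function(th) {
    sa <- th[1]; sp <- th[2]; se <- th[3]
    hinv <- U %*% (t(U) / (sa * lam + sp))
    C <- se * hinv; diag(C) <- diag(C) + D
    cholC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(cholC)) return(NULL)
    Cinv <- chol2inv(cholC)
    vinv <- function(M) {
      ZtM <- rowsum(M, bi, reorder = TRUE)
      if (nrow(ZtM) < q) { # bulls guaranteed present; defensive
        full <- matrix(0, q, ncol(M)); full[as.integer(rownames(ZtM)), ] <- ZtM
        ZtM <- full
      }
      (M - (Cinv %*% ZtM)[bi, , drop = FALSE]) / se
    }
    W <- vinv(X)
    XtW <- crossprod(X, W); XtW <- (XtW + t(XtW)) / 2
    cholXtW <- chol(XtW)
    Fm <- chol2inv(cholXtW)
    Wty <- crossprod(W, y)
    beta <- Fm %*% Wty
    Vy <- vinv(matrix(y)); r <- drop(Vy - W %*% beta)
    ldV <- (n - q) * log(se) + sum(log(sa * lam + sp)) +
      2 * sum(log(diag(cholC)))
    ll <- -0.5 * (ldV + 2 * sum(log(diag(cholXtW))) + sum(y * r))
    list(th = th, ll = ll, W = W, Fm = Fm, r = r, beta = beta,
         Cinv = Cinv, vinv = vinv, se = se)
  }

  st <- eval_at(th)
  if (is.null(st)) stop("variance structure not positive definite at start")
  traj <- data.frame(iter = 0L, sigma_a2 = th[1], sigma_pe2 = th[2],
                     sigma_e2 = th[3], loglik = st$ll)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    sa <- st$th[1]; sp <- st$th[2]; se <- st$th[3]
    W <- st$W; Fm <- st$Fm; r <- st$r
    ty <- drop(rowsum(matrix(r), bi))
    ZtW <- rowsum(W, bi)
    ZtVZ <- -st$Cinv * tcrossprod(D); diag(ZtVZ) <- diag(ZtVZ) + D
    ZtVZ <- ZtVZ / se
    Tm <- ZtVZ - ZtW %*% Fm %*% t(ZtW)
    Gty <- drop(G %*% ty)
    qa <- sum(ty * Gty); qp <- sum(ty^2); qe <- sum(r^2)
    trGT <- sum(G * Tm); trT <- sum(diag(Tm))
    WtW <- crossprod(W)
    trVinv <- (n - sum(diag(st$Cinv) * D)) / se
    trP <- trVinv - sum(Fm * WtW)
    score <- -0.5 * c(trGT - qa, trT - qp, trP - qe)

    vs <- cbind(Gty[bi], ty[bi], r)
    Pv <- st$vinv(vs) - W %*% (Fm %*% crossprod(W, vs))
    AI <- 0.5 * crossprod(vs, Pv); AI <- (AI + t(AI)) / 2

    # components pinned at the lower bound with a downhill score are frozen
    # (active-set); the AI system is solved for the free components only
    act <- !(st$th <= flo * 1.000001 & score < 0)
    delta <- numeric(3)
    if (any(act))
      delta[act] <- tryCatch(
        solve(AI[act, act, drop = FALSE], score[act]),
        error = function(e)
          drop(MASS::ginv(AI[act, act, drop = FALSE]) %*% score[act]))
    emStep <- st$th
    emStep[act] <- st$th[act] +
      (2 * st$th^2 * score / c(q, q, n - p))[act]

    accepted <- NULL
    stp <- delta
    for (h in seq_len(12)) {
      cand <- pmax(st$th + stp, flo)
      ev <- eval_at(cand)
      if (!is.null(ev) && ev$ll >= st$ll - 1e-8) { accepted <- ev; break }
      stp <- stp / 2
    }
    if (is.null(accepted)) {
      cand <- pmax(emStep, flo)
      ev <- eval_at(cand)
      if (!is.null(ev) && ev$ll >= st$ll - 1e-8) accepted <- ev
    }
    if (is.null(accepted)) { converged <- TRUE; break }
    dll <- accepted$ll - st$ll
    dvc <- max(abs(accepted$th - st$th) / pmax(st$th, flo))
    st <- accepted
    traj <- rbind(traj, data.frame(iter = iter, sigma_a2 = st$th[1],
                                   sigma_pe2 = st$th[2], sigma_e2 = st$th[3],
                                   loglik = st$ll))
    if (dvc < tolVc || abs(dll) < tolLl) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("rohdepConvergenceError", "error", "condition"),
      list(message = paste0("AI-REML did not converge in ", maxIter,
                            " iterations"),
           call = sys.call(-1), trajectory = traj))
    stop(cond)
  }
  list(state = st, trajectory = traj, iterations = iter)
}

#' Fit the repeated-records animal model
#'
#' Fits `y = mu + year_season + center + interval + n_sample +
#' b1 * age + (covariates) + animal + perm + e` with `animal ~ N(0, G
#' sigma_a2)` and a per-bull permanent-environment effect `perm ~ N(0, I
#' sigma_pe2)`, by average-information REML (EM fallback on steps that
#' leave the parameter space or decrease the restricted likelihood). Fixed
#' effects are solved by GLS at the converged variance components; each
#' coefficient's `t = estimate / SE` is referred to a Student t with
#' `n_bulls - rank(X)` degrees of freedom, the bull count being the
#' effective replication for per-bull covariates such as inbreeding.
#'
#' Passing a single per-bull inbreeding covariate gives the genome-wide
#' inbreeding-depression regression; passing the five ROH length-class
#' coefficients jointly (see [fitRohClassModel()]) decomposes it by ROH
#' length; passing none gives the base model used for heritability and as
#' the variance-component source for [runScan()].
#'
#' @param ph phenotype `data.frame` for a single trait (see
#'   [readPhenotypes()]).
#' @param grm genomic relationship matrix from [buildGrm()]; must contain
#'   every bull in `ph`.
#' @param inbreeding `NULL`, a named per-bull vector, or a per-bull matrix
#'   (bull ids as rownames, one column per covariate).
#' @param priors starting values `c(sigma_a2, sigma_pe2, sigma_e2)`;
#'   default: phenotypic variance split in equal thirds.
#' @param includeAge include the age-in-months regression (default `TRUE`).
#' @param maxIter,tolVc,tolLl convergence controls: stop when the relative
#'   variance-component change is below `tolVc` (1e-8) or the restricted
#'   log-likelihood change is below `tolLl` (1e-9), at most `maxIter` (200)
#'   iterations; non-convergence is an error carrying the iteration
#'   trajectory.
#' @return A [FitResult-class] object.
#' @export
fitAnimalModel <- function(ph, grm, inbreeding = NULL, priors = NULL,
                           includeAge = TRUE, maxIter = 200L,
                           tolVc = 1e-8, tolLl = 1e-9) {
  stopifnot(is.data.frame(ph), nrow(ph) > 0)
  if (length(unique(ph$trait)) > 1)
    stop("phenotype table contains multiple traits; subset to one")
  bulls <- sort(unique(as.character(ph$bull_id)))
  missG <- setdiff(bulls, rownames(grm))
  if (length(missG))
    stop("bull(s) absent from the GRM: ",
         paste(utils::head(missG), collapse = ", "))
  if (!is.null(inbreeding) && is.null(dim(inbreeding)))
    inbreeding <- matrix(inbreeding, ncol = 1,
                         dimnames = list(names(inbreeding), "f"))
  Xfull <- .buildDesign(ph, covariates = inbreeding,
                        includeAge = includeAge)
  red <- .reduceRank(Xfull)
  y <- as.numeric(ph$value)
  bi <- match(as.character(ph$bull_id), bulls)
  G <- grm[bulls, bulls]
  if (is.null(priors)) priors <- rep(var(y) / 3, 3)
  fit <- .airemlFit(y, red$X, bi, length(bulls), G, priors,
                    maxIter = maxIter, tolVc = tolVc, tolLl = tolLl)
  st <- fit$state
  df <- length(bulls) - red$rank
  est <- se <- rep(NA_real_, length(red$names))
  est[red$keep] <- drop(st$beta)
  se[red$keep] <- sqrt(pmax(diag(st$Fm), 0))
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = max(df, 1))
  coefs <- data.frame(term = red$names, estimate = est, se = se,
                      t = tval, p = pval, stringsAsFactors = FALSE)
  new("FitResult", coefficients = coefs,
      varcomp = setNames(st$th, .vcNames),
      loglik = st$ll, converged = TRUE,
      iterations = as.integer(fit$iterations),
      nRecords = nrow(ph), nBulls = length(bulls), df = as.numeric(df),
      trajectory = fit$trajectory)
}

#' Fit the ROH length-class decomposition model
#'
#' The five length-class inbreeding coefficients are fitted simultaneously
#' as per-bull covariates; a class with zero variance across bulls is
#' reported as `NA`, never dropped silently.
#'
#' @param ph,grm,priors,... as in [fitAnimalModel()].
#' @param fClasses per-bull matrix with bull ids as rownames and the five
#'   class columns (e.g. the `f_roh_*` columns of [inbreedingTable()]).
#' @return A [FitResult-class] object.
#' @export
fitRohClassModel <- function(ph, grm, fClasses, priors = NULL, ...) {
  fClasses <- as.matrix(fClasses)
  if (ncol(fClasses) != 5)
    stop("fClasses must have the five ROH length-class columns")
  fitAnimalModel(ph, grm, inbreeding = fClasses, priors = priors, ...)
}

#' Heritability and repeatability from variance components
#'
#' Heritability `h2 = sigma_a2 / (sigma_a2 + sigma_pe2 + sigma_e2)`;
#' repeatability r is `(sigma_a2 + sigma_pe2)` over the same total.
#' Conventionally reported from the base model fitted without the
#' inbreeding covariate.
#'
#' @param vc named vector (`sigma_a2`, `sigma_pe2`, `sigma_e2`), or a
#'   [FitResult-class] object.
#' @return named vector `c(h2, r)`, with `0 <= h2 <= r <= 1`.
#' @export
heritabilityRepeatability <- function(vc) {
  if (is(vc, "FitResult")) vc <- varComp(vc)
  tot <- sum(vc[.vcNames])
  if (!is.finite(tot) || tot <= 0) stop("total variance must be positive")
  c(h2 = unname(vc["sigma_a2"] / tot),
    r = unname((vc["sigma_a2"] + vc["sigma_pe2"]) / tot))
}
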