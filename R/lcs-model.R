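#' Specification of a latent change score model
#'
#' Defines one member of the four-model group-invariance ladder for a
#' Near/Far outcome pair over two occasions. Each construct is measured by
#' two indicators (first loading fixed to 1, second free, loadings
#' invariant over time and group); the occasion-2 factor is decomposed into
#' the occasion-1 factor plus an explicit latent change, and the structural
#' part regresses the changes on the baseline factors, each other
#' (Near-change to Far-change), and the covariates (IQ and age). The
#' ladder: Model 1 constrains every parameter equal across arms; Model 2
#' frees the two latent change intercepts by arm; Model 3 additionally
#' frees the four baseline-to-change regressions; Model 4 additionally
#' frees the Near-change-to-Far-change regression.
#'
#' @param family `"inhibitory"` (flanker + stop-signal), `"working_memory"`
#'   (Corsi + digit span) or `"cognitive_flexibility"` (card sorting +
#'   dimensional change card sort).
#' @param interval `"t1t2"` (pre to post) or `"t1t3"` (pre to follow-up).
#' @param model_id 1-4, position on the invariance ladder.
#' @param covariates logical, include IQ and age regressions on the
#'   change latents.
#' @return object of class `lcs_spec`.
#' @export
lcs_spec <- function(family = c("inhibitory", "working_memory",
                                "cognitive_flexibility"),
                     interval = c("t1t2", "t1t3"),
                     model_id = 1L, covariates = TRUE) {
  family <- match.arg(family)
  interval <- match.arg(interval)
  if (!model_id %in% 1:4) stop_config("model_id must be 1, 2, 3 or 4")
  near <- switch(family,
                 inhibitory = c("ant_conflict", "osari_ssrt"),
                 working_memory = c("corsi_total", "ds_total"),
                 cognitive_flexibility = c("wcst_prop_err", "dccs_adv"))
  structure(list(family = family, interval = interval,
                 model_id = as.integer(model_id),
                 near_indicators = near,
                 far_indicators = c("brief_gec", "sdq_mean"),
                 covariates = covariates),
            class = "lcs_spec")
}

#' Parameter table for a ladder model
#'
#' Enumerates the free parameters of the model defined by `spec`,
#' marking which are arm-specific offsets. Parameters constrained equal
#' across groups appear once (rendered with an "=" in the ladder tables).
#'
#' @param spec an [lcs_spec()].
#' @return data.frame `name`, `block`, `group_specific`.
#' @export
build_lcs_model <- function(spec) {
  stopifnot(inherits(spec, "lcs_spec"))
  base <- data.frame(
    name = c("muN0", "muF0", "lsdN0", "lsdF0", "zphi0",
             "aN", "aF", "bNN", "bNF", "bFN", "bFF", "cNF",
             "lsdZN", "lsdZF", "lamN", "lamF", "nuN2", "nuF2",
             "lsdE1", "lsdE2", "lsdE3", "lsdE4"),
    block = c(rep("baseline", 5), rep("structural", 7),
              rep("change_variance", 2), rep("measurement", 8)),
    group_specific = FALSE, stringsAsFactors = FALSE)
  if (spec$covariates) {
    base <- rbind(base, data.frame(
      name = c("gNiq", "gNage", "gFiq", "gFage"),
      block = "covariate", group_specific = FALSE))
  }
  if (spec$model_id >= 2) {
    base <- rbind(base, data.frame(name = c("dN", "dF"), block = "structural",
                                   group_specific = TRUE))
  }
  if (spec$model_id >= 3) {
    base <- rbind(base, data.frame(name = c("dbNN", "dbNF", "dbFN", "dbFF"),
                                   block = "structural", group_specific = TRUE))
  }
  if (spec$model_id >= 4) {
    base <- rbind(base, data.frame(name = "dc", block = "structural",
                                   group_specific = TRUE))
  }
  rownames(base) <- NULL
  base
}

lcs_par_init <- function(spec) {
  pn <- build_lcs_model(spec)$name
  init <- stats::setNames(rep(0, length(pn)), pn)
  init[grepl("^lsd", pn)] <- log(0.6)
  init["lamN"] <- 0.5
  init["lamF"] <- 0.5
  init
}

# implied 8-variate normal for one group, conditional on covariates:
# returns mu0 (8), K (8 x 2 covariate slopes), Sigma (8 x 8)
lcs_implied <- function(par, g, covariates = TRUE) {
  gv <- function(nm) if (nm %in% names(par)) par[[nm]] else 0
  aN <- gv("aN") + g * gv("dN")
  aF <- gv("aF") + g * gv("dF")
  bNN <- gv("bNN") + g * gv("dbNN"); bNF <- gv("bNF") + g * gv("dbNF")
  bFN <- gv("bFN") + g * gv("dbFN"); bFF <- gv("bFF") + g * gv("dbFF")
  cNF <- gv("cNF") + g * gv("dc")
  sdN0 <- exp(gv("lsdN0")); sdF0 <- exp(gv("lsdF0"))
  phi <- tanh(gv("zphi0"))
  zN <- exp(gv("lsdZN"))^2; zF <- exp(gv("lsdZF"))^2
  lamN <- gv("lamN"); lamF <- gv("lamF")

  # eta = (N0, F0, dN, dF); eta = alpha + B eta + zeta
  B <- matrix(0, 4, 4)
  B[3, 1:2] <- c(bNN, bNF)
  B[4, ] <- c(bFN, bFF, cNF, 0)
  Minv <- solve(diag(4) - B)
  S <- matrix(0, 4, 4)
  S[1, 1] <- sdN0^2; S[2, 2] <- sdF0^2
  S[1, 2] <- S[2, 1] <- phi * sdN0 * sdF0
  S[3, 3] <- zN; S[4, 4] <- zF
  V <- Minv %*% S %*% t(Minv)

  A <- rbind(c(1, 0, 0, 0), c(lamN, 0, 0, 0),
             c(0, 1, 0, 0), c(0, lamF, 0, 0),
             c(1, 0, 1, 0), c(lamN, 0, lamN, 0),
             c(0, 1, 0, 1), c(0, lamF, 0, lamF))
  nu <- c(0, gv("nuN2"), 0, gv("nuF2"), 0, gv("nuN2"), 0, gv("nuF2"))
  alpha0 <- c(gv("muN0"), gv("muF0"), aN, aF)
  mu0 <- nu + as.numeric(A %*% Minv %*% alpha0)
  K <- NULL
  if (covariates) {
    G <- matrix(0, 4, 2)
    G[3, ] <- c(gv("gNiq"), gv("gNage"))
    G[4, ] <- c(gv("gFiq"), gv("gFage"))
    K <- A %*% Minv %*% G
  }
  Theta <- diag(exp(par[paste0("lsdE", c(1:4, 1:4))])^2)
  Sigma <- A %*% V %*% t(A) + Theta
  list(mu0 = mu0, K = K, Sigma = Sigma)
}

# total log-likelihood of the two-group data under par
lcs_loglik <- function(par, dat, pointwise = FALSE) {
  n <- nrow(dat$Y)
  ll <- numeric(n)
  for (g in 0:1) {
    idx <- which(dat$group == g)
    if (!length(idx)) next
    imp <- lcs_implied(par, g, covariates = !is.null(dat$X))
    ch <- tryCatch(chol(imp$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(if (pointwise) rep(-Inf, n) else -Inf)
    mu <- matrix(imp$mu0, length(idx), 8, byrow = TRUE)
    if (!is.null(dat$X)) mu <- mu + dat$X[idx, , drop = FALSE] %*% t(imp$K)
    R <- dat$Y[idx, , drop = FALSE] - mu
    z <- backsolve(ch, t(R), transpose = TRUE)
    ll[idx] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) - 4 * log(2 * pi)
  }
  if (pointwise) ll else sum(ll)
}

# weakly-informative prior: unit normal on locations and loadings,
# half-normal(1) on SDs (with log-Jacobian), uniform on the baseline
# correlation (with tanh Jacobian)
lcs_logprior <- function(par) {
  nm <- names(par)
  lp <- 0
  loc <- par[!grepl("^(lsd|zphi)", nm)]
  lp <- lp + sum(stats::dnorm(loc, 0, 1, log = TRUE))
  lsd <- par[grepl("^lsd", nm)]
  sd <- exp(lsd)
  lp <- lp + sum(stats::dnorm(sd, 0, 1, log = TRUE) + log(2) + lsd)
  if ("zphi0" %in% nm) {
    z <- par[["zphi0"]]
    lp <- lp + log(0.5) + log(pmax(1 - tanh(z)^2, 1e-12))
  }
  lp
}

lcs_logpost <- function(par, dat) {
  lp <- lcs_logprior(par)
  if (!is.finite(lp)) return(-Inf)
  lp + lcs_loglik(par, dat)
}

#' Simulate data from a latent change score model
#'
#' Draws observations from the model's implied two-group distribution at
#' the supplied generating parameters — the workhorse for
#' parameter-recovery and calibration studies.
#'
#' @param spec an [lcs_spec()].
#' @param par named generating parameters (defaults to
#'   [lcs_true_params()] merged over the model's parameter table).
#' @param n_per_group observations per arm.
#' @param seed integer seed.
#' @return list `Y`, `group`, `X`, `ids` as consumed by [fit_lcs()].
#' @export
simulate_lcs_data <- function(spec, par = lcs_true_params(spec),
                              n_per_group = 200L, seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_group
    group <- rep(0:1, each = n_per_group)
    X <- if (spec$covariates) matrix(stats::rnorm(2 * n), n, 2,
                                     dimnames = list(NULL, c("iq", "age")))
         else NULL
    Y <- matrix(NA_real_, n, 8)
    for (g in 0:1) {
      idx <- which(group == g)
      imp <- lcs_implied(par, g, covariates = spec$covariates)
      ch <- chol(imp$Sigma)
      mu <- matrix(imp$mu0, length(idx), 8, byrow = TRUE)
      if (!is.null(X)) mu <- mu + X[idx, , drop = FALSE] %*% t(imp$K)
      Y[idx, ] <- mu + matrix(stats::rnorm(8 * length(idx)),
                              length(idx), 8) %*% ch
    }
    colnames(Y) <- c("n1_0", "n2_0", "f1_0", "f2_0",
                     "n1_1", "n2_1", "f1_1", "f2_1")
    list(Y = Y, group = group, X = X,
         ids = sprintf("S%04d", seq_len(n)))
  })
}

#' Default generating parameters for simulation studies
#'
#' A plausible, well-identified configuration: unit-scale baseline factors
#' correlated 0.3, moderate negative proportional change, second loadings
#' 0.7, residual SDs 0.5, and zero covariate effects unless overridden.
#'
#' @param spec an [lcs_spec()]; group offsets are included only for the
#'   parameters the model frees.
#' @param overrides named numeric vector merged over the defaults.
#' @return named numeric parameter vector (transformed scale).
#' @export
lcs_true_params <- function(spec, overrides = NULL) {
  par <- lcs_par_init(spec)
  par["muN0"] <- 0; par["muF0"] <- 0
  par["lsdN0"] <- log(0.9); par["lsdF0"] <- log(0.9)
  par["zphi0"] <- atanh(0.3)
  par["aN"] <- 0.2; par["aF"] <- 0.1
  par["bNN"] <- -0.2; par["bNF"] <- 0.1
  par["bFN"] <- 0.1; par["bFF"] <- -0.2
  par["cNF"] <- 0.3
  par["lsdZN"] <- log(0.6); par["lsdZF"] <- log(0.6)
  par["lamN"] <- 0.7; par["lamF"] <- 0.7
  par["nuN2"] <- 0.1; par["nuF2"] <- -0.1
  par[grepl("^lsdE", names(par))] <- log(0.5)
  if (!is.null(overrides)) par[names(overrides)] <- overrides
  par
}
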