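# Cholesky solve of (M + ridge I) x = b with automatic 1e-6 ridge escalation
# when the factorization reports non-positive-definiteness (logged).
.cholSolve <- function(M, b, label = "system") {
  ridge <- 0
  for (k in 0:6) {
    ch <- tryCatch(chol(M + diag(ridge, nrow(M))), error = function(e) NULL)
    if (!is.null(ch))
      return(list(x = backsolve(ch, forwardsolve(t(ch), b)), ridge = ridge))
    ridge <- if (ridge == 0) 1e-6 else ridge * 10
  }
  stop(sprintf("singular %s after regularization", label))
}

#' GBLUP estimated breeding values
#'
#' Solves the single-trait animal model \eqn{y = 1\mu + u + e} with
#' \eqn{var(u) = \sigma_u^2 G} and \eqn{\lambda = \sigma_e^2 / \sigma_u^2 =
#' (1 - h^2) / h^2}, one record per animal:
#' \eqn{\hat{u} = G (G + \lambda I)^{-1} (y - 1\hat{\mu})} with
#' \eqn{\hat{\mu}} the generalized-least-squares mean.  A 1e-6 diagonal
#' ridge is added (and escalated) if the coefficient matrix is not positive
#' definite.
#'
#' @param G a \linkS4class{RelationshipMatrix} (or plain matrix) over the
#'   phenotyped animals.
#' @param phenotypes numeric records, same order as G.
#' @param h2 heritability used for the variance ratio.
#' @return numeric vector of EBVs with attribute \code{mu}.
#' @export
gblupEbv <- function(G, phenotypes, h2) {
  Gm <- if (is(G, "RelationshipMatrix")) relValues(G) else G
  n <- nrow(Gm)
  if (length(phenotypes) != n)
    stop("phenotypes must match the relationship matrix")
  if (anyNA(phenotypes)) stop("phenotypes must be complete")
  lambda <- (1 - h2) / h2
  W <- Gm + diag(lambda, n)
  sol <- .cholSolve(W, cbind(phenotypes, 1), label = "mixed-model equations")
  Winvy <- sol$x[, 1]
  Winv1 <- sol$x[, 2]
  mu <- sum(Winvy) / sum(Winv1)
  u <- as.vector(Gm %*% (Winvy - mu * Winv1))
  attr(u, "mu") <- mu
  u
}

#' Group-coancestry constraint for generation t
#'
#' \eqn{C_t = 1 - (1 - F_0)(1 - \Delta F)^t}: the expected inbreeding level
#' when the base population already carries mean coancestry \eqn{F_0} and
#' inbreeding then accrues at rate \eqn{\Delta F} per generation.
#'
#' @param F0 mean base-population coancestry (mean relationship / 2),
#'   computed with the same matrix used to constrain the OCS.
#' @param dF target rate of inbreeding per generation.
#' @param t generations since the base.
#' @return the constraint value \eqn{C_t}.
#' @export
coancestryConstraint <- function(F0, dF, t) {
  if (F0 >= 1) stop("F0 must be below 1")
  if (dF < 0 || dF >= 1) stop("dF must be in [0, 1)")
  1 - (1 - F0) * (1 - dF)^t
}

# Lagrangian solution with iterative elimination of negative contributions.
# For a fixed active set, write the optimum as c = u + x v with
# u = A^-1 Q (Q'A^-1 Q)^-1 s the minimum-coancestry mix,
# v = A^-1 (g - Q alpha) the projected merit direction (Q'v = 0), and
# x = 1 / (2 lambda).  The cross term u'Av vanishes, so a binding
# constraint c'Ac/2 = C gives x = sqrt((2C - u'Au) / v'Av) in closed form.
# `binding = FALSE` forces x = 0 (the minimum-coancestry solution).
.ocsSolve <- function(ebv, A, sexes, C, binding = TRUE) {
  n <- length(ebv)
  active <- rep(TRUE, n)
  best <- c(which(sexes == 1L)[which.max(ebv[sexes == 1L])],
            which(sexes == 2L)[which.max(ebv[sexes == 2L])])
  s <- c(0.5, 0.5)
  repeat {
    idx <- which(active)
    Q <- cbind(as.numeric(sexes[idx] == 1L), as.numeric(sexes[idx] == 2L))
    As <- A[idx, idx, drop = FALSE]
    sol <- .cholSolve(As, cbind(ebv[idx], Q),
                      label = "OCS coancestry matrix")
    Ag <- sol$x[, 1]
    AQ <- sol$x[, 2:3, drop = FALSE]
    QAQ <- crossprod(Q, AQ)
    beta <- solve(QAQ, s)
    alpha <- solve(QAQ, crossprod(Q, Ag))
    u <- as.vector(AQ %*% beta)
    v <- as.vector(Ag - AQ %*% alpha)
    uAu <- sum(u * (As %*% u))
    vAv <- sum(v * (As %*% v))
    slack <- 2 * C - uAu
    if (binding && slack < 0) {
      # even the minimum-coancestry mix violates the bound
      return(list(ok = FALSE))
    }
    x <- if (!binding || vAv < 1e-14) 0 else sqrt(slack / vAv)
    c_idx <- u + x * v
    neg <- setdiff(idx[c_idx < -1e-12], best)
    if (!length(neg)) {
      cc <- numeric(n)
      cc[idx] <- pmax(c_idx, 0)
      for (sx in c(1L, 2L)) {    # absorb clipping roundoff
        w <- sexes == sx
        cc[w] <- cc[w] * 0.5 / sum(cc[w])
      }
      lambda <- if (x > 0) 1 / (2 * x) else Inf
      l0 <- if (is.finite(lambda)) as.vector(alpha - 2 * lambda * beta) else
        c(NA_real_, NA_real_)
      return(list(ok = TRUE, c = cc, lambda = lambda, lambda0 = l0))
    }
    active[neg] <- FALSE   # batch elimination of negative contributions
  }
}

#' Optimum contribution selection under a group-coancestry constraint
#'
#' Maximizes the merit of the contributions, \eqn{c'\hat{g}}, subject to
#' \eqn{c'Ac/2 \le C}, contributions summing to 1/2 within each sex, and
#' \eqn{c \ge 0}.  Solved by the Lagrangian method with iterative
#' elimination of negative contributions: for a given active set the
#' optimum decomposes into the minimum-coancestry mix plus a multiple of
#' the projected merit direction, and the multiplier of a binding
#' constraint follows in closed form.  When even the unconstrained-merit
#' (truncation) solution
#' satisfies the constraint it is returned directly; when the
#' minimum-achievable coancestry exceeds the constraint, the
#' minimum-coancestry solution is returned with \code{feasible = FALSE}.
#'
#' @param ebv estimated breeding values of the candidates.
#' @param A a \linkS4class{RelationshipMatrix} (or matrix) among candidates.
#' @param sexes integer sex codes (1 = male, 2 = female).
#' @param C upper bound on the group coancestry c'Ac/2.
#' @param ids candidate ids (default 1..n).
#' @return an \linkS4class{OCSolution}.
#' @export
ocsOptimize <- function(ebv, A, sexes, C, ids = NULL) {
  Am <- if (is(A, "RelationshipMatrix")) relValues(A) else A
  n <- length(ebv)
  sexes <- as.integer(sexes)
  if (is.null(ids)) ids <- seq_len(n)
  if (!all(c(1L, 2L) %in% sexes))
    stop("both sexes must be represented among the candidates")
  coan <- function(cc) as.vector(cc %*% Am %*% cc) / 2
  mkSol <- function(cc, lambda, lambda0, feasible) {
    new("OCSolution", contributions = pmax(cc, 0), sexes = sexes,
        ids = as.integer(ids), merit = sum(cc * ebv),
        coancestry = coan(cc), lambda = lambda, lambda0 = lambda0,
        nSelected = sum(cc > 1e-9), feasible = feasible)
  }
  # unconstrained-merit vertex: all weight on the top candidate per sex
  trunc <- numeric(n)
  trunc[which(sexes == 1L)[which.max(ebv[sexes == 1L])]] <- 0.5
  trunc[which(sexes == 2L)[which.max(ebv[sexes == 2L])]] <- 0.5
  if (coan(trunc) <= C + 1e-12)
    return(mkSol(trunc, 0, c(NA_real_, NA_real_), TRUE))
  sol <- .ocsSolve(ebv, Am, sexes, C, binding = TRUE)
  if (!sol$ok) {
    # infeasible bound: return the minimum-coancestry solution, flagged
    smin <- .ocsSolve(ebv, Am, sexes, C, binding = FALSE)
    return(mkSol(smin$c, smin$lambda, smin$lambda0, FALSE))
  }
  mkSol(sol$c, sol$lambda, sol$lambda0, TRUE)
}

#' Sample matings proportional to optimal contributions
#'
#' Every offspring independently draws its sire from the males with
#' probabilities \eqn{2c} and its dam from the females with probabilities
#' \eqn{2c}, with replacement.
#'
#' @param solution an \linkS4class{OCSolution}.
#' @param nOffspring number of matings to draw.
#' @param seed optional integer seed.
#' @return data.frame with columns sire, dam.
#' @export
sampleMatings <- function(solution, nOffspring, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  males <- solution@ids[solution@sexes == 1L]
  pm <- solution@contributions[solution@sexes == 1L]
  females <- solution@ids[solution@sexes == 2L]
  pf <- solution@contributions[solution@sexes == 2L]
  data.frame(
    sire = males[sample.int(length(males), nOffspring, replace = TRUE,
                            prob = pm)],
    dam = females[sample.int(length(females), nOffspring, replace = TRUE,
                             prob = pf)])
}
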