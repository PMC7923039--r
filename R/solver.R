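#' @include simplex.R
NULL

#' Solve a linear program through the uniform solver layer
#'
#' All analyses in the package (FBA, FVA, MFM, reductions) go through
#' this entry point, so they are solver-agnostic and deterministic.  Two
#' back-ends are supported: the package's own warm-startable simplex
#' (default) and an independent dense simplex from \pkg{pracma}
#' (cold-start only), which exists so results can be cross-validated
#' between implementations.
#'
#' @param cost Objective coefficients (length n).
#' @param Aeq,beq Equality constraints \eqn{A x = b} (m x n, length m).
#' @param lower,upper Variable bounds, \code{-Inf}/\code{Inf} allowed.
#' @param direction \code{"max"} or \code{"min"}.
#' @param warmStart Optional basis state from a previous solve on the
#'   same constraints and bounds; never changes the optimum.
#' @param backend \code{"simplex"} (native, warm-startable) or
#'   \code{"pracma"} (independent cross-check; ignores \code{warmStart}).
#' @return List with \code{status} (\code{"optimal"} /
#'   \code{"infeasible"} / \code{"unbounded"}), \code{x}, \code{objective}
#'   and \code{state} for warm starting.
#'
#' @examples
#' # maximize v subject to v <= 10
#' solveLP(1, matrix(0, 0, 1), numeric(0), 0, 10, "max")$objective
#' @export
solveLP <- function(cost, Aeq, beq, lower, upper,
                    direction = c("max", "min"), warmStart = NULL,
                    backend = c("simplex", "pracma")) {
    direction <- match.arg(direction)
    backend <- match.arg(backend)
    if (backend == "simplex") {
        return(simplexSolve(cost, Aeq, beq, lower, upper,
                            maximize = direction == "max",
                            warmStart = warmStart))
    }
    .pracmaLP(cost, Aeq, beq, lower, upper, direction)
}

## Independent back-end: pracma::linprog expects min c'z with z >= 0 and
## A z <= b / Aeq z = beq.  Variables are shifted by their finite lower
## bound; variables with lower bound -Inf are split into a difference of
## two nonnegative parts.  Finite upper bounds become inequality rows.
.pracmaLP <- function(cost, Aeq, beq, lower, upper, direction) {
    n <- length(cost)
    Aeq <- as.matrix(Aeq)
    cap <- function(v) pmin(pmax(v, -BIG_BOUND), BIG_BOUND)
    lo <- cap(lower); hi <- cap(upper)
    cols <- list(); cc <- numeric(0); shift <- numeric(n)
    map <- vector("list", n)
    for (j in seq_len(n)) {
        aj <- if (nrow(Aeq)) Aeq[, j] else numeric(0)
        if (is.finite(lower[j])) {
            shift[j] <- lo[j]
            cols[[length(cols) + 1L]] <- aj
            cc <- c(cc, cost[j])
            map[[j]] <- c(length(cols), NA)
        } else {
            shift[j] <- 0
            cols[[length(cols) + 1L]] <- aj
            cols[[length(cols) + 1L]] <- -aj
            cc <- c(cc, cost[j], -cost[j])
            map[[j]] <- c(length(cols) - 1L, length(cols))
        }
    }
    Az <- if (nrow(Aeq)) do.call(cbind, cols) else
        matrix(0, 0, length(cc))
    bz <- beq - if (nrow(Aeq)) as.numeric(Aeq %*% shift) else numeric(0)
    ## inequality rows for finite upper bounds (and lower caps of split vars)
    Ain <- NULL; bin <- NULL
    for (j in seq_len(n)) {
        row <- numeric(length(cc))
        row[map[[j]][1L]] <- 1
        if (!is.na(map[[j]][2L])) row[map[[j]][2L]] <- -1
        if (is.finite(upper[j]) || !is.finite(lower[j])) {
            Ain <- rbind(Ain, row)
            bin <- c(bin, hi[j] - shift[j])
        }
        if (!is.finite(lower[j])) {   # cap the split at -BIG_BOUND
            Ain <- rbind(Ain, -row)
            bin <- c(bin, -lo[j])
        }
    }
    res <- tryCatch(
        pracma::linprog(cc, A = Ain, b = bin, Aeq = if (nrow(Az)) Az else NULL,
                        beq = if (nrow(Az)) bz else NULL,
                        maximize = direction == "max", maxiter = 10000),
        error = function(e) NULL
    )
    if (is.null(res) || is.null(res$x)) {
        return(list(status = "infeasible", x = NULL, objective = NA_real_,
                    state = NULL))
    }
    x <- vapply(seq_len(n), function(j) {
        v <- res$x[map[[j]][1L]]
        if (!is.na(map[[j]][2L])) v <- v - res$x[map[[j]][2L]]
        v + shift[j]
    }, numeric(1))
    list(status = "optimal", x = x, objective = sum(cost * x), state = NULL)
}

#' Solve a convex quadratic program
#'
#' Minimizes \eqn{\frac{1}{2} x' Q x + d' x} subject to equality
#' constraints and box bounds, for symmetric positive-semidefinite
#' \eqn{Q}.  Feasibility is established first with a simplex phase-1 run,
#' so infeasible problems are reported cleanly.  The solve itself is a
#' primal active-set method over the box constraints: starting from the
#' phase-1 point, each iteration projects onto the affine set defined by
#' the equalities and the currently pinned variables (an exact
#' least-squares solve of the KKT system, tolerant of redundant
#' stoichiometric rows), takes the longest feasible step toward that
#' projection, and pins or releases bounds by their Lagrange
#' multipliers until the KKT conditions hold.
#'
#' @param Q Symmetric PSD matrix (n x n); must be positive definite on
#'   the null space of the equality constraints (the identity-weighted
#'   distance of MOMA always is).
#' @param d Linear term (length n).
#' @param Aeq,beq Equality constraints.
#' @param lower,upper Bounds; infinities are replaced by the documented
#'   finite cap of \eqn{\pm 10^6}.
#' @return List with \code{status}, \code{x}, and \code{objective}
#'   (the value of the quadratic form at the optimum).
#'
#' @examples
#' # minimize (v - 3)^2 on [0, 10]
#' solveQP(matrix(2), -6, matrix(0, 0, 1), numeric(0), 0, 10)$x + 0
#' @export
solveQP <- function(Q, d, Aeq, beq, lower, upper) {
    n <- length(d)
    Aeq <- as.matrix(Aeq)
    if (n && max(abs(Q - t(Q))) > 1e-9) {
        stop("quadratic term must be symmetric")
    }
    feas <- simplexSolve(rep(0, n), Aeq, beq, lower, upper)
    if (feas$status != "optimal") {
        return(list(status = "infeasible", x = NULL, objective = NA_real_))
    }
    lo <- pmax(lower, -BIG_BOUND)
    hi <- pmin(upper, BIG_BOUND)
    x0 <- pmin(pmax(feas$x, lo), hi)
    x <- .activeSetQP(Q, d, Aeq, beq, lo, hi, x0)
    resid <- if (nrow(Aeq)) max(abs(Aeq %*% x - beq)) else 0
    if (resid > 1e-6 || any(x < lo - 1e-6) || any(x > hi + 1e-6)) {
        stop("quadratic solver returned an infeasible point (residual ",
             format(resid), ")")
    }
    list(status = "optimal", x = x,
         objective = as.numeric(0.5 * t(x) %*% Q %*% x + sum(d * x)))
}

## Minimal-norm least-squares solve via SVD (tolerant of rank
## deficiency; the KKT systems below are consistent by construction).
.lstsq <- function(M, rhs) {
    if (!nrow(M) || !ncol(M)) return(numeric(ncol(M)))
    sv <- svd(M)
    tol <- max(dim(M)) * max(sv$d[1L], 0) * 1e-12
    pos <- sv$d > tol
    if (!any(pos)) return(numeric(ncol(M)))
    as.numeric(sv$v[, pos, drop = FALSE] %*%
                   ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos]))
}

## Primal active-set QP over equalities + boxes, from a feasible point.
## state per variable: 0 free, -1 pinned at lower, +1 pinned at upper.
.activeSetQP <- function(Q, d, A, b, lo, hi, x0, tol = 1e-9) {
    n <- length(d)
    m <- nrow(A)
    v <- x0
    state <- integer(n)
    state[v <= lo + tol] <- -1L
    state[v >= hi - tol] <- 1L
    fixedVar <- hi - lo <= 1e-12       # never released
    state[fixedVar] <- -1L
    maxit <- 100L * (n + 1L)
    for (it in seq_len(maxit)) {
        Free <- which(state == 0L)
        Act <- which(state != 0L)
        vA <- ifelse(state[Act] < 0L, lo[Act], hi[Act])
        v[Act] <- vA
        nf <- length(Free)
        if (nf) {
            ## projection onto {A_F v_F = b - A_A v_A} under Q:
            ## exact KKT least-squares solve
            AF <- A[, Free, drop = FALSE]
            K <- rbind(
                cbind(Q[Free, Free, drop = FALSE], t(AF)),
                cbind(AF, matrix(0, m, m))
            )
            rhs <- c(
                -d[Free] - if (length(Act)) {
                    as.numeric(Q[Free, Act, drop = FALSE] %*% vA)
                } else {
                    0
                },
                b - if (length(Act)) {
                    as.numeric(A[, Act, drop = FALSE] %*% vA)
                } else {
                    0
                }
            )
            sol <- .lstsq(K, rhs)
            vF <- sol[seq_len(nf)]
            mu <- sol[nf + seq_len(m)]
            step <- vF - v[Free]
            ## longest feasible step toward the projection
            alpha <- 1
            hit <- 0L
            hitSide <- 0L
            for (k in seq_len(nf)) {
                j <- Free[k]
                if (step[k] > tol && is.finite(hi[j])) {
                    a <- (hi[j] - v[j]) / step[k]
                    if (a < alpha - 1e-12) { alpha <- a; hit <- j; hitSide <- 1L }
                } else if (step[k] < -tol && is.finite(lo[j])) {
                    a <- (lo[j] - v[j]) / step[k]
                    if (a < alpha - 1e-12) { alpha <- a; hit <- j; hitSide <- -1L }
                }
            }
            alpha <- max(0, min(1, alpha))
            v[Free] <- v[Free] + alpha * step
            if (hit) {
                state[hit] <- hitSide
                v[hit] <- if (hitSide < 0L) lo[hit] else hi[hit]
                next
            }
        } else {
            ## all variables pinned: best multiplier estimate
            mu <- .lstsq(t(A), -(as.numeric(Q %*% v) + d))
        }
        ## KKT: release the worst mis-signed bound multiplier
        eta <- as.numeric(Q %*% v) + d + as.numeric(crossprod(A, mu))
        rel <- 0L
        worst <- tol * 10
        for (j in which(state != 0L)) {
            if (fixedVar[j]) next
            viol <- if (state[j] < 0L) -eta[j] else eta[j]
            if (viol > worst) { worst <- viol; rel <- j }
        }
        if (!rel) {
            return(v)
        }
        state[rel] <- 0L
    }
    stop("active-set iteration limit reached in quadratic solver")
}
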