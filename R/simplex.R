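## Bounded-variable two-phase revised simplex with basis warm starts.
##
## This is the package's LP engine.  Warm starts are what make the
## fastFVA-style loops (fva, mfm) cheap: consecutive solves share the
## constraint matrix and bounds and differ only in the cost vector, so an
## optimal basis of one solve is a feasible starting basis of the next
## and phase 1 can be skipped entirely.
##
## Problems solved:  min/max  c'x   s.t.  A x = b,  l <= x <= u
## with l, u allowed to be -Inf/Inf.  Dense linear algebra: the models
## this package targets stay small after dead-end reduction, and the
## matrix is refactorized each iteration for numerical robustness.

PIV_TOL <- 1e-10   # smallest pivot magnitude accepted in the ratio test
RED_TOL <- 1e-9    # reduced-cost optimality tolerance
FEAS_TOL <- 1e-7   # residual infeasibility threshold after phase 1

## Nonbasic value implied by a variable's status.
.nonbasicValue <- function(stat, lower, upper) {
    ifelse(stat == "L", lower, ifelse(stat == "U", upper, 0))
}

#' Solve a bounded-variable linear program
#'
#' Two-phase primal simplex over equality constraints and box bounds,
#' with optional warm starting from a previous basis.  A warm start never
#' changes the optimum, only the work needed to reach it; it is accepted
#' only when the stored basis is still primal feasible for the current
#' bounds, and silently falls back to a cold start otherwise.
#'
#' @param cost Numeric cost vector (length n).
#' @param A Equality constraint matrix (m x n; dense or sparse).
#' @param b Right-hand side (length m).
#' @param lower,upper Variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize Maximize instead of minimize?
#' @param warmStart Optional \code{state} element of a previous result on
#'   the same constraints and bounds.
#' @param maxit Iteration cap (default scales with problem size).
#' @return List with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{x} (primal solution, present when
#'   optimal), \code{objective}, and \code{state} (opaque basis for warm
#'   starting).
#'
#' @examples
#' # maximize x + y  s.t.  x + y = 1, 0 <= x, y <= 1
#' simplexSolve(c(1, 1), matrix(c(1, 1), 1), 1, c(0, 0), c(1, 1),
#'     maximize = TRUE)$objective
#' @export
simplexSolve <- function(cost, A, b, lower, upper, maximize = FALSE,
                         warmStart = NULL, maxit = NULL) {
    n <- length(cost)
    A <- as.matrix(A)
    m <- nrow(A)
    stopifnot(ncol(A) == n, length(b) == m,
              length(lower) == n, length(upper) == n)
    if (any(lower > upper)) {
        return(list(status = "infeasible", x = NULL, objective = NA_real_,
                    state = NULL))
    }
    csign <- if (maximize) -cost else cost

    if (n == 0L) {
        status <- if (all(abs(b) <= FEAS_TOL)) "optimal" else "infeasible"
        return(list(status = status,
                    x = if (status == "optimal") numeric(0) else NULL,
                    objective = if (status == "optimal") 0 else NA_real_,
                    state = NULL))
    }
    if (m == 0L) {
        ## pure box problem: each variable to its best bound
        x <- ifelse(csign > 0, lower, ifelse(csign < 0, upper,
            ifelse(is.finite(lower), lower, ifelse(is.finite(upper), upper, 0))))
        if (any(!is.finite(x[csign != 0]))) {
            return(list(status = "unbounded", x = NULL,
                        objective = NA_real_, state = NULL))
        }
        x[!is.finite(x)] <- 0
        obj <- sum(cost * x)
        return(list(status = "optimal", x = x, objective = obj, state = NULL))
    }

    ## augment with one artificial per row (identity signed by residual)
    nt <- n + m
    lowerAll <- c(lower, rep(0, m))
    art <- (n + 1L):nt
    if (is.null(maxit)) maxit <- 100L * (nt + 20L)

    runPhase <- function(Aall, cvec, stat, basis, lowerAll, upperAll,
                         blandAfter) {
        iter <- 0L
        repeat {
            iter <- iter + 1L
            if (iter > maxit) stop("simplex iteration limit reached")
            Bmat <- Aall[, basis, drop = FALSE]
            nonbasic <- setdiff(seq_len(ncol(Aall)), basis)
            xN <- .nonbasicValue(stat[nonbasic], lowerAll[nonbasic],
                                 upperAll[nonbasic])
            rhs <- b - as.numeric(Aall[, nonbasic, drop = FALSE] %*% xN)
            lu <- tryCatch(solve(Bmat, cbind(rhs, cvec[basis] * 0)),
                           error = function(e) NULL)
            if (is.null(lu)) return(NULL)   # singular basis (bad warm start)
            xB <- lu[, 1L]
            y <- tryCatch(solve(t(Bmat), cvec[basis]),
                          error = function(e) NULL)
            if (is.null(y)) return(NULL)
            d <- cvec[nonbasic] - as.numeric(crossprod(Aall[, nonbasic,
                                                            drop = FALSE], y))
            up <- (stat[nonbasic] %in% c("L", "F")) & d < -RED_TOL
            dn <- (stat[nonbasic] %in% c("U", "F")) & d > RED_TOL
            cand <- which(up | dn)
            if (!length(cand)) {
                return(list(stat = stat, basis = basis, xB = xB,
                            nonbasic = nonbasic, xN = xN,
                            objective = sum(cvec[basis] * xB) + sum(
                                cvec[nonbasic] * xN)))
            }
            if (iter > blandAfter) {
                k <- cand[which.min(nonbasic[cand])]
            } else {
                k <- cand[which.max(abs(d[cand]))]
            }
            e <- nonbasic[k]
            tdir <- if (up[k]) 1 else -1
            w <- solve(Bmat, Aall[, e])
            g <- tdir * w
            lim <- rep(Inf, m)
            pos <- g > PIV_TOL
            neg <- g < -PIV_TOL
            lim[pos] <- pmax(0, (xB[pos] - lowerAll[basis[pos]]) / g[pos])
            lim[neg] <- pmax(0, (xB[neg] - upperAll[basis[neg]]) / g[neg])
            span <- upperAll[e] - lowerAll[e]   # bound-flip distance
            delta <- min(lim, span)
            if (!is.finite(delta)) {
                return(list(unbounded = TRUE))
            }
            if (delta >= span - 1e-15 && is.finite(span) &&
                span <= min(lim)) {
                ## entering variable runs to its opposite bound
                stat[e] <- if (stat[e] == "L") "U" else "L"
                next
            }
            ties <- which(abs(lim - delta) <= 1e-12 & is.finite(lim))
            if (!length(ties)) ties <- which.min(lim)
            if (iter > blandAfter) {
                r <- ties[which.min(basis[ties])]
            } else {
                r <- ties[which.max(abs(g[ties]))]
            }
            leav <- basis[r]
            stat[leav] <- if (g[r] > 0) "L" else "U"
            if (!is.finite(lowerAll[leav]) && stat[leav] == "L") stat[leav] <- "F"
            if (!is.finite(upperAll[leav]) && stat[leav] == "U") stat[leav] <- "F"
            stat[e] <- "B"
            basis[r] <- e
        }
    }

    coldStart <- function() {
        statOrig <- ifelse(is.finite(lower), "L",
                           ifelse(is.finite(upper), "U", "F"))
        x0 <- .nonbasicValue(statOrig, lower, upper)
        r <- b - as.numeric(A %*% x0)
        s <- ifelse(r >= 0, 1, -1)
        Aall <- cbind(A, diag(s, nrow = m))
        stat <- c(statOrig, rep("B", m))
        basis <- art
        upperAll <- c(upper, rep(Inf, m))
        c1 <- c(rep(0, n), rep(1, m))
        ph1 <- runPhase(Aall, c1, stat, basis, lowerAll, upperAll,
                        blandAfter = 5L * nt + 50L)
        if (is.null(ph1)) stop("numerically singular basis in phase 1")
        if (isTRUE(ph1$unbounded)) stop("phase 1 cannot be unbounded")
        if (ph1$objective > FEAS_TOL) {
            return(list(infeasible = TRUE))
        }
        list(Aall = Aall, stat = ph1$stat, basis = ph1$basis)
    }

    warm <- NULL
    if (!is.null(warmStart) &&
        length(warmStart$stat) == nt && length(warmStart$basis) == m) {
        Aall <- cbind(A, warmStart$signs)
        upperAll <- c(upper, rep(0, m))
        nonbasic <- setdiff(seq_len(nt), warmStart$basis)
        xN <- .nonbasicValue(warmStart$stat[nonbasic], lowerAll[nonbasic],
                             upperAll[nonbasic])
        Bmat <- Aall[, warmStart$basis, drop = FALSE]
        xB <- tryCatch(
            solve(Bmat, b - as.numeric(Aall[, nonbasic, drop = FALSE] %*% xN)),
            error = function(e) NULL
        )
        if (!is.null(xB) &&
            all(xB >= lowerAll[warmStart$basis] - FEAS_TOL) &&
            all(xB <= upperAll[warmStart$basis] + FEAS_TOL)) {
            warm <- list(Aall = Aall, stat = warmStart$stat,
                         basis = warmStart$basis)
        }
    }
    start <- if (!is.null(warm)) warm else coldStart()
    if (isTRUE(start$infeasible)) {
        return(list(status = "infeasible", x = NULL, objective = NA_real_,
                    state = NULL))
    }

    ## phase 2: artificials pinned to zero
    upperAll <- c(upper, rep(0, m))
    c2 <- c(csign, rep(0, m))
    ph2 <- runPhase(start$Aall, c2, start$stat, start$basis, lowerAll,
                    upperAll, blandAfter = 5L * nt + 50L)
    if (is.null(ph2)) {
        if (!is.null(warm)) {  # stale basis: retry cold
            return(simplexSolve(cost, A, b, lower, upper, maximize,
                                warmStart = NULL, maxit = maxit))
        }
        stop("numerically singular basis in phase 2")
    }
    if (isTRUE(ph2$unbounded)) {
        return(list(status = "unbounded", x = NULL, objective = NA_real_,
                    state = NULL))
    }
    x <- numeric(nt)
    x[ph2$basis] <- ph2$xB
    x[ph2$nonbasic] <- ph2$xN
    xOrig <- x[seq_len(n)]
    signs <- start$Aall[, art, drop = FALSE]
    list(
        status = "optimal",
        x = xOrig,
        objective = sum(cost * xOrig),
        state = list(stat = ph2$stat, basis = ph2$basis, signs = signs)
    )
}
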