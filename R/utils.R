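# numeric helpers shared across modules

.logsumexp <- function(x) {
    if (!length(x)) return(-Inf)
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf at equality and
# tolerates sub-epsilon inversions from floating-point summation
.logdiffexp <- function(a, b) {
    if (b == -Inf) return(a)
    if (a < b) {
        if (b - a < 1e-9) return(-Inf)
        stop("logdiffexp requires a >= b")
    }
    if (a == b) return(-Inf)
    a + log1p(-exp(b - a))
}

.zToP <- function(z) 2 * pnorm(-abs(z))

# complement a vector of A/C/G/T alleles
.complement <- function(a) {
    c(A = "T", C = "G", G = "C", T = "A")[a]
}

.isPalindromic <- function(ea, oa) {
    (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# multivariate normal draw given a correlation matrix via Cholesky;
# adds a small ridge if the factorization fails (warned)
.rmvnormChol <- function(n, mu, R, sd) {
    L <- tryCatch(chol(R), error = function(e) {
        warning("LD matrix not positive definite; ridge regularization applied")
        chol(R + diag(1e-6, nrow(R)))
    })
    z <- matrix(rnorm(n * nrow(R)), n, nrow(R)) %*% L
    sweep(z, 2L, sd, `*`) + matrix(mu, n, length(mu), byrow = TRUE)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
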