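#' Extensible worm-like-chain force-extension model
#'
#' The Marko-Siggia interpolation with an enthalpic stretch term:
#' `F = (kT/Lp) * (1/(4(1-l)^2) - 1/4 + l)` with the effective fractional
#' extension `l = x/Lc - F/K`, where `Lc` is the contour length (nm), `Lp`
#' the persistence length (nm) and `K` the stretch modulus (pN).  The
#' relation is implicit in both directions; `wlc_force()` solves for force
#' at given extension and `wlc_extension()` for extension at given force,
#' both by safeguarded vectorized Newton iteration.
#'
#' @param x Extension(s), nm.
#' @param F Force(s), pN.
#' @param Lc Contour length, nm.
#' @param Lp Persistence length, nm.
#' @param K Stretch modulus, pN.
#' @return `wlc_force()`: force(s) in pN; `wlc_extension()`: extension(s) in nm.
#' @examples
#' wlc_extension(10, Lc = 850, Lp = 45, K = 1200)
#' wlc_force(800, Lc = 850, Lp = 45, K = 1200)
#' @export
wlc_force <- function(x, Lc, Lp, K) {
  stopifnot(Lc > 0, Lp > 0, K > 0)
  a <- kT / Lp
  # start from a guess keeping l strictly below 1
  l0 <- pmin(x / Lc, 0.97)
  F <- a * (1 / (4 * (1 - l0)^2) - 0.25 + l0)
  F <- pmax(F, K * (x / Lc - 0.97))  # enforce l <= 0.97 at the start
  for (it in 1:60) {
    l <- x / Lc - F / K
    l <- pmin(l, 1 - 1e-9)
    g <- a * (1 / (4 * (1 - l)^2) - 0.25 + l) - F
    dg <- a * (1 / (2 * (1 - l)^3) + 1) * (-1 / K) - 1
    step <- g / dg
    F_new <- F - step
    # l decreases as F grows, so the iteration cannot cross the singularity
    F <- F_new
    if (max(abs(step)) < 1e-12 * max(1, max(abs(F)))) break
  }
  F
}

#' @rdname wlc_force
#' @export
wlc_extension <- function(F, Lc, Lp, K) {
  stopifnot(Lc > 0, Lp > 0, K > 0)
  a <- kT / Lp
  l <- rep(0.5, length(F))
  for (it in 1:80) {
    h <- a * (1 / (4 * (1 - l)^2) - 0.25 + l) - F
    dh <- a * (1 / (2 * (1 - l)^3) + 1)
    step <- h / dh
    l <- pmin(pmax(l - step, 0), 1 - 1e-9)
    if (max(abs(step)) < 1e-14) break
  }
  Lc * (l + F / K)
}
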