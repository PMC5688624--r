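#' Kinetic parameters of the miRNA-sponge model
#'
#' Mass-action ceRNA titration system: an endogenous target transcript
#' T, an intron-retaining sponge transcript S carrying
#' \code{n_sites_S} miRNA binding sites, and a miRNA M that binds
#' either RNA into complexes C_TM / C_SM. Rates: transcription k_*
#' (molecules/time), first-order degradation d_* (1/time), association
#' a_* (1/(molecules x time)), dissociation u_* (1/time), complex
#' decay d_complex. With \code{catalytic = TRUE} the miRNA is recycled
#' when a complex decays; otherwise decay is stoichiometric and
#' removes the miRNA too.
#'
#' @param k_T,k_S,k_M transcription rates
#' @param d_T,d_S,d_M degradation rates
#' @param d_complex complex decay rate
#' @param a_TM,a_SM association rates
#' @param u_TM,u_SM dissociation rates
#' @param n_sites_S binding sites per sponge transcript (>= 1)
#' @param catalytic logical; miRNA recycled on complex decay
#' @return list of class \code{SpongeParams}
#' @export
spongeParams <- function(k_T = 10, k_S = 0, k_M = 20,
                         d_T = 0.1, d_S = 0.1, d_M = 0.05,
                         d_complex = 0.5,
                         a_TM = 0.01, a_SM = 0.01,
                         u_TM = 0.02, u_SM = 0.02,
                         n_sites_S = 4, catalytic = FALSE) {
    p <- as.list(environment())
    rates <- setdiff(names(p), "catalytic")
    if (any(unlist(p[rates]) < 0)) stop("all rates must be >= 0")
    if (n_sites_S < 1) stop("n_sites_S must be >= 1")
    class(p) <- "SpongeParams"
    p
}

#' Time derivatives of the sponge system
#'
#' State: free target T, free sponge S, free miRNA M, complexes C_TM
#' and C_SM. Sponge binding is boosted by its site multiplicity
#' (effective association a_SM * n_sites_S).
#'
#' @param state named numeric (T, S, M, C_TM, C_SM)
#' @param params a \code{\link{spongeParams}}
#' @return named numeric of derivatives
#' @export
spongeDerivatives <- function(state, params) {
    with(c(as.list(state), params), {
        aS <- a_SM * n_sites_S
        recyc <- if (catalytic) d_complex else 0
        c(T = k_T - d_T * T - a_TM * T * M + u_TM * C_TM,
          S = k_S - d_S * S - aS * S * M + u_SM * C_SM,
          M = k_M - d_M * M - a_TM * T * M - aS * S * M +
              u_TM * C_TM + u_SM * C_SM +
              recyc * C_TM + recyc * C_SM,
          C_TM = a_TM * T * M - u_TM * C_TM - d_complex * C_TM,
          C_SM = aS * S * M - u_SM * C_SM - d_complex * C_SM)
    })
}

#' Integrate the sponge system
#'
#' Stiff-safe adaptive integration (lsoda) at fixed default tolerances
#' 1e-8 (relative) / 1e-6 (absolute).
#'
#' @param params a \code{\link{spongeParams}}
#' @param init named initial state; zeros by default
#' @param times output time grid
#' @param rtol,atol solver tolerances
#' @return matrix (deSolve trajectory): time + state columns
#' @export
simulateSponge <- function(params,
                           init = c(T = 0, S = 0, M = 0,
                                    C_TM = 0, C_SM = 0),
                           times = seq(0, 200, by = 1),
                           rtol = 1e-8, atol = 1e-6) {
    f <- function(t, y, p) list(spongeDerivatives(y, p))
    out <- deSolve::ode(y = init, times = times, func = f,
                        parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    unclass(out)
}

#' Steady state of the sponge system
#'
#' Integrates over doubling horizons until the derivative norm falls
#' below \code{tol} (relative to state magnitude).
#'
#' @param params a \code{\link{spongeParams}}
#' @param init initial state
#' @param tol convergence tolerance on max |dx/dt| / (1 + |x|)
#' @param t_max giving-up horizon
#' @return named numeric steady state
#' @export
spongeSteadyState <- function(params,
                              init = c(T = 0, S = 0, M = 0,
                                       C_TM = 0, C_SM = 0),
                              tol = 1e-8, t_max = 1e6) {
    state <- init
    horizon <- 100
    repeat {
        tr <- simulateSponge(params, state, times = c(0, horizon))
        state <- tr[nrow(tr), -1]
        d <- spongeDerivatives(state, params)
        if (max(abs(d) / (1 + abs(state))) < tol) break
        horizon <- horizon * 2
        if (horizon > t_max)
            stop("no steady state within t_max (non-dissipative parameters?)")
    }
    state
}

#' Sponge dose-response curve
#'
#' Steady-state free target abundance as a function of sponge
#' transcription rate; the derepression ratio is T at the largest k_S
#' over T at k_S = 0.
#'
#' @param params a \code{\link{spongeParams}} (its k_S is ignored)
#' @param k_S_grid sponge transcription rates to scan
#' @return list(curve = data.frame(k_S, T_free), derepression_ratio)
#' @export
spongeDoseResponse <- function(params, k_S_grid = seq(0, 100, by = 10)) {
    tf <- vapply(k_S_grid, function(ks) {
        p <- params
        p$k_S <- ks
        unname(spongeSteadyState(p)["T"])
    }, numeric(1))
    base <- {
        p <- params; p$k_S <- 0
        unname(spongeSteadyState(p)["T"])
    }
    list(curve = data.frame(k_S = k_S_grid, T_free = tf),
         derepression_ratio = tf[length(tf)] / base)
}
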