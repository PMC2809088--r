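# Unified nearest-neighbor duplex thermodynamics (SantaLucia 1998),
# used to pick probe lengths toward a common hybridization temperature.
# dH in kcal/mol, dS in cal/(mol K), for the ten Watson-Crick stacks;
# initiation terms depend on the terminal base pair.

.nn_dimers <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG",
                "TT", "TG", "AC", "AG", "TC", "CC")
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9)
# initiation: terminal G.C pair vs terminal A.T pair
.nn_init_dh <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
.nn_init_ds <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)
.gas_const <- 1.987  # cal/(mol K)

#' Duplex melting temperature by nearest-neighbor thermodynamics
#'
#' Computes the predicted melting temperature of a probe hybridized to
#' its perfect complement using the unified nearest-neighbor parameter
#' set, an entropic monovalent-salt correction of
#' `0.368 * (N - 1) * ln[Na+]` (N = probe length), and the
#' `R * ln(CT/4)` concentration term for non-self-complementary duplexes:
#'
#' `Tm = 1000 * dH / (dS + salt + R * ln(CT/4)) - 273.15`
#'
#' Reverse-complement sequences have identical Tm (duplex symmetry).
#'
#' @param sequence character vector of probe sequences (A/C/G/T only,
#'   length >= 8).
#' @param na_conc monovalent cation concentration, molar.
#' @param probe_conc total strand concentration CT, molar.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
compute_tm <- function(sequence, na_conc = 0.05, probe_conc = 2.5e-7) {
  stopifnot(is.character(sequence), na_conc > 0, probe_conc > 0)
  vapply(sequence, function(s) {
    s <- toupper(s)
    if (!nzchar(s) || grepl("[^ACGT]", s)) {
      stop("compute_tm: sequence must be non-empty A/C/G/T only", call. = FALSE)
    }
    n <- nchar(s)
    if (n < 8L) stop("compute_tm: sequence shorter than 8 bases", call. = FALSE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    dimer <- paste0(ch[-n], ch[-1])
    dh <- sum(.nn_dh[dimer]) + .nn_init_dh[ch[1]] + .nn_init_dh[ch[n]]
    ds <- sum(.nn_ds[dimer]) + .nn_init_ds[ch[1]] + .nn_init_ds[ch[n]]
    ds_corr <- ds + 0.368 * (n - 1) * log(na_conc)
    1000 * dh / (ds_corr + .gas_const * log(probe_conc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}
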