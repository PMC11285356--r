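# Nearest-neighbor melting-temperature engine.
#
# Unified duplex parameters of Allawi & SantaLucia (1997): per-stack
# dH (kcal/mol) and dS (cal/mol/K), terminal initiation terms, a
# sodium correction applied to the entropy, and the standard two-state
# Tm equation
#
#   Tm = 1000 * dH / (dS + R * ln(CT)) - 273.15
#
# with R = 1.987 cal/mol/K and CT the effective strand concentration
# (dnac1 - dnac2/2, in mol/L) for non-self-complementary duplexes.
# Defaults (25 nM each strand, 50 mM Na+) match the defaults of the
# widespread scripting-ecosystem implementation of this model, so that
# designs are interchangeable with tools built on it.

# base encoding A=1 C=2 G=3 T=4; stack index = 4*(b1-1)+b2
.NN_DH <- c(
  -7.9, -8.4, -7.8, -7.2,   # AA AC AG AT
  -8.5, -8.0, -10.6, -7.8,  # CA CC CG CT
  -8.2, -9.8, -8.0, -8.4,   # GA GC GG GT
  -7.2, -8.2, -8.5, -7.9    # TA TC TG TT
)
.NN_DS <- c(
  -22.2, -22.4, -21.0, -20.4,
  -22.7, -19.9, -27.2, -21.0,
  -22.2, -24.4, -19.9, -22.4,
  -21.3, -22.2, -22.7, -22.2
)
# terminal initiation: one term per duplex end
.INIT_AT_DH <- 2.3
.INIT_AT_DS <- 4.1
.INIT_GC_DH <- 0.1
.INIT_GC_DS <- -2.8
.GAS_R <- 1.987

#' Melting-temperature model parameters
#'
#' The thermodynamic conditions used by [melting_temperature]. Kept in
#' one place so the whole design pipeline is computed under a single,
#' explicit parameterization.
#'
#' @param dnac1,dnac2 Strand concentrations in nM (higher/lower).
#' @param na Monovalent sodium concentration in mM.
#' @param min_len Minimum duplex length in nt for which the
#'   nearest-neighbor model is trusted; shorter queries are an error.
#' @return A list of class `tm_parameters`.
#' @export
tm_parameters <- function(dnac1 = 25, dnac2 = 25, na = 50, min_len = 8L) {
  stopifnot(dnac1 > 0, dnac2 >= 0, na > 0, min_len >= 2)
  structure(
    list(dnac1 = dnac1, dnac2 = dnac2, na = na, min_len = as.integer(min_len)),
    class = "tm_parameters"
  )
}

# encode an ACGT string as integer codes 1..4 (after validation)
.encode_bases <- function(seq) {
  .check_acgt(seq)
  match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
}

# entropy term shared by every duplex of length n at these conditions
.salt_ds <- function(n, tm_par) {
  0.368 * (n - 1) * log(tm_par$na * 1e-3)
}

.conc_term <- function(tm_par) {
  .GAS_R * log((tm_par$dnac1 - tm_par$dnac2 / 2) * 1e-9)
}

.tm_from_sums <- function(dh, ds, n, tm_par) {
  1000 * dh / (ds + .salt_ds(n, tm_par) + .conc_term(tm_par)) - 273.15
}

.init_dh <- function(code) ifelse(code %in% c(1L, 4L), .INIT_AT_DH, .INIT_GC_DH)
.init_ds <- function(code) ifelse(code %in% c(1L, 4L), .INIT_AT_DS, .INIT_GC_DS)

#' Nearest-neighbor melting temperature
#'
#' Computes the duplex melting temperature (degrees Celsius) of each
#' sequence against its perfect complement under the nearest-neighbor
#' model described in [tm_parameters]. By construction the result is
#' identical for a sequence and its reverse complement, so overlap Tm
#' values apply equally to sense and antisense fragment sets.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T, length >=
#'   `tm_par$min_len`).
#' @param tm_par Model conditions, see [tm_parameters].
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, tm_par = tm_parameters()) {
  stopifnot(is.character(seq), inherits(tm_par, "tm_parameters"))
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < tm_par$min_len) {
      stop(
        "sequence too short for the nearest-neighbor model (", n,
        " nt < minimum ", tm_par$min_len, " nt)", call. = FALSE
      )
    }
    b <- .encode_bases(s)
    stack <- 4L * (b[-n] - 1L) + b[-1L]
    dh <- sum(.NN_DH[stack]) + .init_dh(b[1L]) + .init_dh(b[n])
    ds <- sum(.NN_DS[stack]) + .init_ds(b[1L]) + .init_ds(b[n])
    .tm_from_sums(dh, ds, n, tm_par)
  }, numeric(1), USE.NAMES = FALSE)
}

# Tm of every suffix (lengths kmin..kmax) of `context` in one O(n)
# pass, via reverse-cumulative stack sums. Used by the overlap search,
# where per-suffix calls would dominate the screening cost.
# Returns a numeric vector named by suffix length.
.suffix_tms <- function(context, kmin, kmax, tm_par) {
  b <- .encode_bases(context)
  n <- length(b)
  stopifnot(kmax <= n, kmin >= 2)
  stack <- 4L * (b[-n] - 1L) + b[-1L]
  # cum_dh[j] = sum of stacks j..n-1  (suffix of length k starts at n-k+1)
  cum_dh <- rev(cumsum(rev(.NN_DH[stack])))
  cum_ds <- rev(cumsum(rev(.NN_DS[stack])))
  ks <- kmin:kmax
  starts <- n - ks + 1L
  dh <- cum_dh[starts] + .init_dh(b[starts]) + .init_dh(b[n])
  ds <- cum_ds[starts] + .init_ds(b[starts]) + .init_ds(b[n])
  tm <- 1000 * dh / (ds + .salt_ds(ks, tm_par) + .conc_term(tm_par)) - 273.15
  names(tm) <- ks
  tm
}

# Tm of every prefix (lengths kmin..kmax); used by gene-primer design.
.prefix_tms <- function(context, kmin, kmax, tm_par) {
  b <- .encode_bases(context)
  n <- length(b)
  stopifnot(kmax <= n, kmin >= 2)
  stack <- 4L * (b[-n] - 1L) + b[-1L]
  cum_dh <- cumsum(.NN_DH[stack])
  cum_ds <- cumsum(.NN_DS[stack])
  ks <- kmin:kmax
  dh <- cum_dh[ks - 1L] + .init_dh(b[1L]) + .init_dh(b[ks])
  ds <- cum_ds[ks - 1L] + .init_ds(b[1L]) + .init_ds(b[ks])
  tm <- 1000 * dh / (ds + .salt_ds(ks, tm_par) + .conc_term(tm_par)) - 273.15
  names(tm) <- ks
  tm
}
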