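# Element tables used by the mass-weighted metrics and the atomic form-factor
# model. Masses in Da; form factors are the standard four-Gaussian
# Cromer-Mann parameterisations, f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c.

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, ZN = 65.38, FE = 55.845, MG = 24.305, CA = 40.078,
  `NA` = 22.990, K = 39.098, CL = 35.45, MN = 54.938, CU = 63.546,
  SE = 78.971, BD = 1.0
)

# Atomic numbers (f(0) for the neutral atom); BD is the unit toy bead.
.element_z <- c(
  H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, ZN = 30, FE = 26,
  MG = 12, CA = 20, `NA` = 11, K = 19, CL = 17, MN = 25, CU = 29,
  SE = 34, BD = 1
)

.cromer_mann <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  ZN = list(a = c(14.0743, 7.03180, 5.16520, 2.41000),
            b = c(3.26550, 0.233300, 10.3163, 58.7097), c = 1.30410)
)

# Residue electron counts (neutral residue within a chain, hydrogens included)
# used by the one-bead-per-residue form-factor model.
.residue_electrons <- c(
  GLY = 30, ALA = 38, SER = 46, PRO = 52, VAL = 54, THR = 54, CYS = 54,
  ILE = 62, LEU = 62, ASN = 60, ASP = 59, GLN = 68, LYS = 71, GLU = 67,
  MET = 70, HIS = 72, PHE = 78, ARG = 84, TYR = 86, TRP = 98
)

#' Look up atomic masses for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da. Unknown elements fall back to the
#'   mass of carbon with a warning, mirroring the tolerant behaviour of
#'   trajectory-analysis tools when coordinate files omit element metadata.
#' @export
element_mass <- function(element) {
  key <- toupper(element)
  m <- unname(.element_masses[key])
  if (anyNA(m)) {
    warn(paste0(
      "Unknown element symbol(s): ",
      paste(unique(key[is.na(m)]), collapse = ", "),
      "; using the mass of carbon."
    ))
    m[is.na(m)] <- .element_masses[["C"]]
  }
  m
}

# f(q) per element on a q grid, as a length(q) x n_elements matrix.
# model "unit": f == 1. model "atomic": Cromer-Mann (fallback: constant Z).
form_factor_matrix <- function(element, q, model = c("unit", "residue", "atomic")) {
  model <- match.arg(model)
  key <- toupper(element)
  nq <- length(q)
  if (model == "unit") {
    return(matrix(1, nrow = nq, ncol = length(key)))
  }
  if (model == "residue") {
    abort("residue form factors require per-residue beads; use residue_form_factors()")
  }
  s2 <- (q / (4 * pi))^2
  res <- vapply(key, function(el) {
    cm <- .cromer_mann[[el]]
    if (is.null(cm)) {
      z <- .element_z[[el]]
      if (is.null(z) || is.na(z)) z <- 6
      rep(z, nq)
    } else {
      colSums(cm$a * exp(-outer(cm$b, s2))) + cm$c
    }
  }, numeric(nq), USE.NAMES = FALSE)
  if (!is.matrix(res)) res <- matrix(res, nrow = nq)
  res
}

# Effective electron count per residue bead; unknown residue names get the
# mean of the table (a generic residue).
residue_electron_count <- function(resname) {
  key <- toupper(resname)
  e <- unname(.residue_electrons[key])
  e[is.na(e)] <- mean(.residue_electrons)
  e
}
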