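# Cromer-Mann 4-Gaussian coefficients (International Tables Vol. C, neutral
# atoms): f(s) = sum_i a_i exp(-b_i s^2) + c with s = sin(theta)/lambda in
# Å^-1. Covers the elements common in macromolecular models plus frequent
# ligand/metal atoms.
.cromer_mann <- local({
  tab <- rbind(
    H  = c(0.493002, 0.322912, 0.140191, 0.040810, 10.5109, 26.1257, 3.14236, 57.7997, 0.003038),
    C  = c(2.31000, 1.02000, 1.58860, 0.865000, 20.8439, 10.2075, 0.568700, 51.6512, 0.215600),
    N  = c(12.2126, 3.13220, 2.01250, 1.16630, 0.005700, 9.89330, 28.9975, 0.582600, -11.529),
    O  = c(3.04850, 2.28680, 1.54630, 0.867000, 13.2771, 5.70110, 0.323900, 32.9089, 0.250800),
    Na = c(4.76260, 3.17360, 1.26740, 1.11280, 3.28500, 8.84220, 0.313600, 129.424, 0.676000),
    Mg = c(5.42040, 2.17350, 1.22690, 2.30730, 2.82750, 79.2611, 0.380800, 7.19370, 0.858400),
    P  = c(6.43450, 4.17910, 1.78000, 1.49080, 1.90670, 27.1570, 0.526000, 68.1645, 1.11490),
    S  = c(6.90530, 5.20340, 1.43790, 1.58630, 1.46790, 22.2151, 0.253600, 56.1720, 0.866900),
    Cl = c(11.4604, 7.19640, 6.25560, 1.64550, 0.010400, 1.16620, 18.5194, 47.7784, -9.55740),
    K  = c(8.21860, 7.43980, 1.05190, 0.865900, 12.7949, 0.774800, 213.187, 41.6841, 1.42280),
    Ca = c(8.62660, 7.38730, 1.58990, 1.02110, 10.4421, 0.659900, 85.7484, 178.437, 1.37510),
    Mn = c(11.2819, 7.35730, 3.01930, 2.24410, 5.34090, 0.343200, 17.8674, 83.7543, 1.08960),
    Fe = c(11.7695, 7.35730, 3.52220, 2.30450, 4.76110, 0.307200, 15.3535, 76.8805, 1.03690),
    Ni = c(12.8376, 7.29200, 4.44380, 2.38000, 3.87850, 0.256500, 12.1763, 66.3421, 1.03410),
    Cu = c(13.3380, 7.16760, 5.61580, 1.67350, 3.58280, 0.247000, 11.3966, 64.8126, 1.19100),
    Zn = c(14.0743, 7.03180, 5.16525, 2.41000, 3.26550, 0.233300, 10.3163, 58.7097, 1.30410)
  )
  colnames(tab) <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4", "c")
  tab
})

#' Elements with a tabulated atomic form factor
#' @return Character vector of chemical symbols.
#' @export
known_elements <- function() rownames(.cromer_mann)

#' Atomic scattering (form) factor
#'
#' Evaluates the 4-Gaussian Cromer-Mann approximation
#' f(s) = sum a_i exp(-b_i s^2) + c for a neutral atom, with
#' s = sin(theta)/lambda in Å^-1 (i.e. half the scattering-vector length).
#' f(0) equals the element's electron count to tabulation accuracy, and f
#' is non-increasing in s for neutral atoms.
#'
#' @param element Chemical symbol (see [known_elements()]).
#' @param s sin(theta)/lambda in Å^-1; any non-negative numeric vector.
#' @return Numeric vector of scattering amplitudes in electrons.
#' @examples
#' form_factor("C", 0) # ~ 6 electrons
#' @export
form_factor <- function(element, s) {
  if (length(element) != 1 || !element %in% known_elements()) {
    rlang::abort(paste0("unknown element '", paste(element, collapse = ","),
                        "'; tabulated symbols: ", paste(known_elements(), collapse = ", ")))
  }
  if (any(s < 0)) rlang::abort("`s` = sin(theta)/lambda must be non-negative")
  p <- .cromer_mann[element, ]
  s2 <- s^2
  p[["a1"]] * exp(-p[["b1"]] * s2) + p[["a2"]] * exp(-p[["b2"]] * s2) +
    p[["a3"]] * exp(-p[["b3"]] * s2) + p[["a4"]] * exp(-p[["b4"]] * s2) + p[["c"]]
}
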