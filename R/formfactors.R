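# 4-term Cromer-Mann X-ray scattering-factor coefficients
# (International Tables for Crystallography Vol. C):
# f(s) = sum_i a_i exp(-b_i s^2) + c, with s = sin(theta)/lambda = 1/(2d).
# Elements outside this table fall back to a point scatterer f = Z.
cromer_mann <- list(
  H  = list(z = 1,  a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C  = list(z = 6,  a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(z = 7,  a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290),
  O  = list(z = 8,  a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(z = 15, a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(z = 16, a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  Cl = list(z = 17, a = c(11.4604, 7.19640, 6.25560, 1.64550),
            b = c(0.010400, 1.16620, 18.5194, 47.7784), c = -9.55740),
  Fe = list(z = 26, a = c(11.7695, 7.35730, 3.52220, 2.30450),
            b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690),
  Mo = list(z = 42, a = c(3.70250, 17.2356, 12.8876, 3.74290),
            b = c(0.277200, 1.09580, 11.0040, 61.6584), c = 4.38750),
  Ba = list(z = 56, a = c(20.3361, 19.2970, 10.8880, 2.69590),
            b = c(3.21600, 0.275600, 20.2073, 167.202), c = 2.77310)
)

element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
  Ar = 18, K = 19, Ca = 20, Ti = 22, Cr = 24, Mn = 25, Fe = 26, Co = 27,
  Ni = 28, Cu = 29, Zn = 30, Se = 34, Br = 35, Mo = 42, I = 53, Ba = 56
)

#' Atomic number of an element symbol
#' @param element Character vector of element symbols (e.g. `"Fe"`).
#' @return Integer atomic numbers.
#' @export
atomic_number <- function(element) {
  el <- normalize_element(element)
  z <- element_numbers[el]
  if (any(is.na(z)))
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  unname(z)
}

normalize_element <- function(element) {
  el <- sub("[0-9+'-]*$", "", trimws(element))
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

# scattering factor curve for one element at stol = sin(theta)/lambda = 1/(2d)
scattering_factor <- function(element, stol) {
  el <- normalize_element(element)
  cm <- cromer_mann[[el]]
  if (is.null(cm)) {
    # point scatterer: flat curve at the atomic number
    rep(atomic_number(el), length(stol))
  } else {
    s2 <- stol^2
    f <- rep(cm$c, length(stol))
    for (i in 1:4) f <- f + cm$a[i] * exp(-cm$b[i] * s2)
    f
  }
}
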