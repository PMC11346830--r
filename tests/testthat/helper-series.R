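# Shared fixtures for the test suite.

# One built-in series as a (year, value) tibble.
builtin_series <- function(name) {
  dplyr::filter(jilin_health_resources(), indicator == name) |>
    dplyr::select(year, value)
}

# Published reference values for the six Jilin series: least-squares
# parameters, adequacy statistics, and the accuracy grade of each fit.
reference_fits <- tibble::tribble(
  ~indicator,             ~a,      ~b,          ~C,     ~P,    ~grade,
  "medical_institutions", -0.0376, 19515.8506,  0.1535, 0.875, 2L,
  "medical_beds",         -0.0273, 147551.9272, 0.0711, 1.000, 1L,
  "health_technicians",   -0.0517, 152234.9888, 0.0497, 1.000, 1L,
  "licensed_physicians",  -0.0414, 65552.8446,  0.0522, 1.000, 1L,
  "registered_nurses",    -0.0766, 57921.8695,  0.0562, 1.000, 1L,
  "pharmacists",          -0.0213, 7566.6949,   0.1531, 1.000, 1L
)

# Published 2025 forecasts (nearest integer).
reference_2025 <- c(
  medical_institutions = 28999, medical_beds = 196328,
  health_technicians = 262219, licensed_physicians = 101273,
  registered_nurses = 129586, pharmacists = 9469
)

# A random positive near-exponential series for property tests: exact grey
# recursion parameters drawn at random, multiplicative lognormal noise.
random_series <- function(n = 8) {
  a <- stats::runif(1, -0.15, -0.005)
  b <- stats::runif(1, 50, 5000)
  x1 <- stats::runif(1, 0.5, 1.2) * b
  gm11_simulate(a, b, x1, n, noise_sd = stats::runif(1, 0, 0.05))
}
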