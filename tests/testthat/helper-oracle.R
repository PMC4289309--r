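# Independent brute-force recursive-Fresnel oracle (interface-by-interface
# amplitude recursion), coded separately from the package's
# characteristic-matrix implementation.

oracle_csqrt <- function(z) {
  s <- sqrt(as.complex(z))
  ifelse(Im(s) < 0, -s, s)
}

# eps: complex permittivities, d_nm: thicknesses (NA for semi-infinite ends)
oracle_reflectance <- function(eps, d_nm, theta_deg, wavelength_nm,
                               polarization = "p") {
  k0 <- 2 * pi / wavelength_nm
  kx2 <- Re(eps[1]) * sin(theta_deg * pi / 180)^2
  N <- length(eps)
  kz <- k0 * oracle_csqrt(eps - kx2)
  r_if <- function(i, j) {
    if (polarization == "p")
      (eps[j] * kz[i] - eps[i] * kz[j]) / (eps[j] * kz[i] + eps[i] * kz[j])
    else
      (kz[i] - kz[j]) / (kz[i] + kz[j])
  }
  R <- r_if(N - 1, N)
  if (N > 2) for (j in (N - 1):2) {
    phase <- exp(2i * kz[j] * d_nm[j])
    R <- (r_if(j - 1, j) + R * phase) / (1 + r_if(j - 1, j) * R * phase)
  }
  Mod(R)^2
}

oracle_stack_reflectance <- function(stack, theta_deg, polarization = "p") {
  vapply(theta_deg, function(a)
    oracle_reflectance(stack$eps, stack$thickness_nm, a,
                       stack$wavelength_nm, polarization), 0)
}

# random 3-5 layer stack: transparent entry medium, mixed lossy/lossless
# interior films, dielectric exit medium
random_stack <- function(seed, lossless = FALSE) {
  set.seed(seed)
  n_layers <- sample(3:5, 1)
  layers <- vector("list", n_layers)
  layers[[1]] <- optical_layer("entry", index = runif(1, 1.4, 1.9))
  for (j in 2:(n_layers - 1)) {
    eps <- if (lossless) complex(real = runif(1, 1.5, 6)) else
      complex(real = runif(1, -12, 6), imaginary = runif(1, 0, 4))
    layers[[j]] <- optical_layer(paste0("film", j),
                                 thickness_nm = runif(1, 5, 200),
                                 permittivity = eps)
  }
  layers[[n_layers]] <- optical_layer("exit", index = runif(1, 1.3, 1.6))
  optical_stack(layers, wavelength_nm = runif(1, 450, 700))
}
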