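# Reference murine parameter estimates (WT and WASP-deficient strains) and
# small reusable fixtures. All datasets are generated in code.

ref_params <- list(
  wt_wt     = list(rd = 1.16, ls = 105, sd = 0.180, pr = 20.5, n = 240),
  wt_wasp   = list(rd = 1.55, ls = 105, sd = 0.275),
  wasp_wasp = list(rd = 4.20, ls = 150, sd = 0.18, pr = 24.4, n = 500),
  wasp_wt   = list(rd = 2.28, ls = 106, sd = 0.231)
)

# A fast, well-equilibrated regime for unit tests (short lifespan).
fast_params <- function(rd = 2, ls = 40, sd = 0.2, pr = 1)
  kinetic_params(rd, ls, sd, pr)

fast_space <- function(points = 5)
  search_space(rd = c(1, 3), ls = c(30, 50), sd = c(0.1, 0.3), points = points)

# Noiseless dataset generated exactly at a grid node of fast_space().
fast_node_data <- function(n_subjects = 3)
  simulate_consumption(fast_params(), n_subjects = n_subjects, noise_sd = 0,
                       equilibration_hr = 300)
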