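# Shared fixtures and independent oracles.

# atomic units with their dimension vectors and scales to the mg/m/day base,
# kept independent of the package's registry so dimension bookkeeping can be
# cross-checked by brute force
oracle_units <- list(
  mg  = list(dim = c(1, 0, 0),  scale = 1),
  g   = list(dim = c(1, 0, 0),  scale = 1e3),
  kg  = list(dim = c(1, 0, 0),  scale = 1e6),
  m   = list(dim = c(0, 1, 0),  scale = 1),
  cm  = list(dim = c(0, 1, 0),  scale = 1e-2),
  um  = list(dim = c(0, 1, 0),  scale = 1e-6),
  l   = list(dim = c(0, 3, 0),  scale = 1e-3),
  ul  = list(dim = c(0, 3, 0),  scale = 1e-9),
  day = list(dim = c(0, 0, 1),  scale = 1),
  h   = list(dim = c(0, 0, 1),  scale = 1 / 24)
)

# reference one-compartment quantities, closed form
oracle_steady_state <- function(D, t_half) D * t_half / log(2)
oracle_trajectory <- function(D, t_half, t) {
  k <- log(2) / t_half
  (D / k) * (1 - exp(-k * t))
}

# numeric ODE integration of dB/dt = D - k B (independent of the package's
# analytic solution)
ode_trajectory <- function(D, t_half, times) {
  k <- log(2) / t_half
  out <- deSolve::ode(
    y = c(B = 0), times = c(0, times),
    func = function(t, y, p) list(D - k * y[1]),
    rtol = 1e-10, atol = 1e-12)
  as.numeric(out[-1, "B"])
}

# the reference nine-row sensitivity grid, printed cells
printed_grid <- data.frame(
  label = paste0("row", 1:9),
  noaec = c(0.53, 0.63, 1.21, 2.66, 5.07, 0.63, 1.21, 2.66, 5.07),
  af_lungburden = c(0.93, 1.52, 0.76, 1.52, 0.76, 1.52, 0.76, 1.52, 0.76),
  af_clearance = c(0.93, 0.93, 0.93, 0.93, 0.93, 0.58, 0.58, 0.58, 0.58),
  hec = c(0.53, 1.03, 0.98, 4.33, 4.14, 1.65, 1.58, 6.93, 6.62))
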