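# shared fixtures: reference parameters and a few geometries
ref_params <- make_params()
open_geom <- function(n1 = 0, n2 = 0) egfr_geometry("open", n1, n2, ref_params)
closed_geom <- function(n1 = 0, n2 = 0) egfr_geometry("closed", n1, n2, ref_params)

# reference asymmetric deformation configuration used across tests
ref_asym <- list(
  geom = protein_geometry(1.6, 2 * ref_params$h_r, 0.5, -0.2),
  Rd = 5.6, Ru = 8.6
)

# random admissible configuration generator (deterministic under set.seed)
random_config <- function(params = ref_params) {
  Rp <- runif(1, 0.9, 4)
  topo <- sample(1:3, 1)
  L <- sort(runif(2, 2, 8))
  conf <- switch(topo,
    c(Rp, Rp),                       # single region
    c(Rp + L[1], Rp + L[1]),         # coincident annuli (two regions)
    c(Rp + L[1], Rp + L[2])          # staggered annuli (three regions)
  )
  list(
    geom = protein_geometry(Rp, 2 * params$h_r,
                            n1 = runif(1, -0.7, 0.7), n2 = runif(1, -0.7, 0.7)),
    Rd = conf[1], Ru = conf[2]
  )
}
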