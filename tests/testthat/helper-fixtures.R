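# shared fixtures, built once per test run and cached
.fx <- new.env()

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_helix20 <- function() fx_get("helix20", function() make_structure(20, "helix"))

fx_bundle60 <- function() fx_get("bundle60", function() make_structure(60, "bundle"))

fx_maps60 <- function() fx_get("maps60", function() {
  simulate_halfmaps(fx_bundle60(), resolution = 3, voxel = 1,
                    noise_sigma = 0.3, seeds = c(101L, 202L))
})

fx_rama <- function() default_rama_potential()

# small random map on a unit grid
fx_noise_map <- function(n = 16L, seed = 1L, voxel = 1) {
  set.seed(seed)
  density_map(array(rnorm(n^3), c(n, n, n)), voxel = voxel)
}
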