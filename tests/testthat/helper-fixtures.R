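# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

# small landscape + 15 heterogeneous individuals + design-level table
small_study <- function() {
  fixture("small_study", function() {
    ras <- generate_landscapes(n_rows = 128, n_cols = 128, seed = 401)
    gamma <- draw_individual_coefficients(15, seed = 402)
    centres <- simulate_home_centres(15, ras, radius = 2500, seed = 403)
    tab <- simulate_used_available(ras, gamma, centres, n_used = 150,
                                   n_avail = 1500, seed = 404)
    list(rasters = ras, gamma = gamma, centres = centres, table = tab)
  })
}

small_fit <- function() {
  fixture("small_fit", function()
    fit_hierarchical_rsf(small_study()$table, rsf_model_spec(),
                         method = "map"))
}

# constant and ramp rasters for covariate-extraction oracles
ramp_rasters <- function() {
  ramp <- outer(1:10, 1:10, function(r, c) c + 10 * (r - 1)) # 1..100
  list(de = raster_surface(matrix(5, 10, 10), cell_size = 10),
       lion = raster_surface(ramp, cell_size = 10),
       wolf = raster_surface(matrix(1, 10, 10), cell_size = 10))
}

# telemetry with a regular sub-daily schedule
regular_telemetry <- function(id = "a", start = "2012-07-01",
                              days = 4, per_day = 48, x = 0, y = 0) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  step <- 86400 %/% per_day
  shift <- min(1800, step %/% 2)  # first fix of each day at 00:30 (or 00:15)
  stamps <- t0 + rep((seq_len(days) - 1) * 86400, each = per_day) +
    rep((seq_len(per_day) - 1) * step, days) + shift
  data.frame(animal_id = id, timestamp = stamps,
             x = x + seq_along(stamps), y = y + seq_along(stamps))
}

unit_square_hr <- function() {
  home_range(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
}
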