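# Small in-code fixtures shared across test files.

tiny_walls <- function() {
  data.frame(
    wall_id = c("W1", "W2", "W3", "W4"),
    trip_id = c("T1", "T1", "T1", "T1"),
    boat_id = c("B1", "B1", "B1", "B1"),
    net_id = c("N1", "N1", "N2", "N2"),
    wall_index = c(1L, 2L, 1L, 2L),
    wall_type = c("PMF", "PMF", "MMF", "MMF"),
    depth_m = c(80, 85, 90, 95),
    soak_h = c(44, 44, 46, 46),
    stringsAsFactors = FALSE)
}

tiny_items <- function() {
  data.frame(
    item_id = c("I1", "I2", "I3"),
    wall_id = c("W1", "W3", "NET_LEVEL"),
    species = c("Scorpaena scrofa", "Raja sp.", "Porifera"),
    fate = c("MARKETABLE", "DISCARD", "DISCARD"),
    length_cm = c(25, NA, NA),
    length_class_upper_cm = c(NA, 40, NA),
    weight_kg = c(NA, NA, 0.3),
    alive_on_arrival = c(NA, FALSE, NA),
    commercial_category = c("Scorpaena scrofa", NA, NA),
    stringsAsFactors = FALSE)
}

tiny_pools <- function() {
  data.frame(
    net_id = c("N1", "N1"),
    total_volume_l = c(40, 40),
    subsample_volume_l = c(20, 20),
    species = c("Lithothamnion spp.", "Posidonia oceanica"),
    subsample_weight_kg = c(0.5, 0.2),
    stringsAsFactors = FALSE)
}

tiny_lw <- function() {
  data.frame(species = c("Scorpaena scrofa", "Raja sp."),
             a = c(0.01, 0.004), b = c(3, 3.1),
             length_type = c("TOTAL_LENGTH", "TOTAL_LENGTH"),
             units = c("g_cm", "g_cm"), stringsAsFactors = FALSE)
}

tiny_prices <- function() {
  data.frame(commercial_category = c("Scorpaena scrofa", "Scorpaena scrofa"),
             trip_id = c("T1", "T2"),
             price_eur_per_kg = c(17, 18.36), stringsAsFactors = FALSE)
}

write_tiny_tables <- function(dir = tempfile("tabs")) {
  dir.create(dir)
  write_catch_tables(list(walls = tiny_walls(), items = tiny_items(),
                          pools = tiny_pools(), prices = tiny_prices(),
                          lw = tiny_lw()), dir)
  dir
}

# small synthetic survey used by several files (fast to generate)
small_sim <- function(seed = 5, ...) {
  simulate_catch(sim_config(nets_per_boat = c(4, 3, 3), walls_per_net = 8,
                            seed = seed, ...))
}
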