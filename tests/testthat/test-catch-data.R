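# Deterministic catch-processing rules and file I/O.

test_that("catch tables round-trip through csv and validate", {
  dir <- write_tiny_tables()
  tabs <- read_catch_tables(file.path(dir, "walls.csv"),
                            file.path(dir, "items.csv"),
                            file.path(dir, "pools.csv"))
  expect_equal(tabs$walls, tiny_walls())
  expect_equal(tabs$items, tiny_items())
  expect_equal(tabs$pools, tiny_pools())

  # a full simulated dataset round-trips structurally
  sim <- small_sim()
  dir2 <- tempfile("sim")
  write_catch_tables(sim, dir2)
  back <- read_catch_tables(file.path(dir2, "walls.csv"),
                            file.path(dir2, "items.csv"),
                            file.path(dir2, "pools.csv"))
  unrow <- function(d) { rownames(d) <- NULL; d }
  expect_equal(unrow(back$walls), unrow(sim$walls), tolerance = 1e-12)
  expect_equal(unrow(back$items[, names(back$items) != "length_cm"]),
               unrow(sim$items[, names(sim$items) != "length_cm"]))
  expect_equal(back$items$length_cm, sim$items$length_cm, tolerance = 1e-10)
})

test_that("empty items file with a valid header parses to an empty list", {
  dir <- write_tiny_tables()
  items_path <- file.path(dir, "items.csv")
  writeLines(readLines(items_path)[1], items_path)
  tabs <- read_catch_tables(file.path(dir, "walls.csv"), items_path,
                            file.path(dir, "pools.csv"))
  expect_equal(nrow(tabs$items), 0L)
  expect_equal(nrow(tabs$walls), 4L)
})

test_that("parse errors name the file and the offending row", {
  dir <- write_tiny_tables()
  items <- tiny_items()
  items$wall_id[2] <- "NOPE"
  utils::write.csv(items, file.path(dir, "items.csv"), row.names = FALSE,
                   na = "")
  expect_error(read_catch_tables(file.path(dir, "walls.csv"),
                                 file.path(dir, "items.csv"),
                                 file.path(dir, "pools.csv")),
               "items.csv.*row 2.*NOPE")

  walls <- tiny_walls()
  walls$wall_type[1] <- "NYLON"
  utils::write.csv(walls, file.path(dir, "walls.csv"), row.names = FALSE,
                   na = "")
  expect_error(read_catch_tables(file.path(dir, "walls.csv"),
                                 file.path(dir, "items.csv"),
                                 file.path(dir, "pools.csv")),
               "walls.csv.*wall_type")

  # missing column
  dir2 <- write_tiny_tables()
  w <- utils::read.csv(file.path(dir2, "walls.csv"))
  w$depth_m <- NULL
  utils::write.csv(w, file.path(dir2, "walls.csv"), row.names = FALSE)
  expect_error(read_catch_tables(file.path(dir2, "walls.csv"),
                                 file.path(dir2, "items.csv"),
                                 file.path(dir2, "pools.csv")),
               "missing column.*depth_m")
})

test_that("length-weight conversion matches direct evaluation and is monotone", {
  expect_equal(length_to_weight(10, a = 0.01, b = 3), 0.01)
  expect_equal(length_to_weight(1, a = 1, b = 1), 0.001)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.001, 2); b <- runif(1, 1, 4); L <- runif(1, 1, 120)
    expect_equal(length_to_weight(L, a, b), a * L^b / 1000)
    # homogeneous in a, strictly increasing in length
    expect_equal(length_to_weight(L, 2 * a, b),
                 2 * length_to_weight(L, a, b))
    expect_gt(length_to_weight(L + 1, a, b), length_to_weight(L, a, b))
  }
  expect_error(length_to_weight(-3, 0.01, 3), "positive")
})

test_that("length classes are half-open with the boundary in the lower class", {
  expect_equal(assign_length_class(23, 10), 30)
  expect_equal(assign_length_class(20, 10), 20)
  expect_equal(assign_length_class(7.1, 5), 10)
  set.seed(2)
  L <- runif(200, 0.01, 200)
  up <- assign_length_class(L, 10)
  expect_true(all(up - L >= 0 & up - L < 10))
  # exact boundaries map to themselves
  expect_equal(assign_length_class(c(10, 50, 0.5), c(10, 10, 0.1)),
               c(10, 50, 0.5))
  expect_error(assign_length_class(0, 10), "positive")
})

test_that("length imputation pools measured lengths and class upper bounds", {
  items <- data.frame(species = rep("X", 3),
                      length_cm = c(10, 20, NA),
                      length_class_upper_cm = c(NA, NA, NA))
  expect_equal(impute_length(items, "X"), 15)
  items2 <- data.frame(species = "X", length_cm = 12,
                       length_class_upper_cm = NA)
  expect_equal(impute_length(items2, "X"), 12)
  items3 <- data.frame(species = c("X", "X"), length_cm = c(11, NA),
                       length_class_upper_cm = c(NA, 30))
  expect_equal(impute_length(items3, "X"), 20.5)
  expect_error(impute_length(items3, "Y"), "drop or flag")
})

test_that("item revenue uses the mean category price over trips", {
  prices <- data.frame(commercial_category = c("A", "A"),
                       trip_id = c("T1", "T2"),
                       price_eur_per_kg = c(40, 44))
  expect_equal(item_revenue(1, "A", prices), 42)
  expect_equal(item_revenue(0, "A", prices), 0)
  one <- data.frame(commercial_category = "S", trip_id = "T1",
                    price_eur_per_kg = 17.68)
  expect_equal(item_revenue(0.5, "S", one), 8.84)
  expect_error(item_revenue(1, "B", prices), "absent")
})

test_that("net-level pooling scales the subsample linearly by volume", {
  # 0.5 kg in a 20-L subsample of a 40-L total -> 1.0 kg
  pool <- data.frame(net_id = "N1", total_volume_l = 40,
                     subsample_volume_l = 20, species = "maerl",
                     subsample_weight_kg = 0.5)
  none <- tiny_items()[0, ]
  expect_equal(pool_discards_to_net(none, pool), c(maerl = 1.0))

  # no pool fraction: wall-level sums unchanged
  it <- data.frame(item_id = c("a", "b"), wall_id = c("W1", "W2"),
                   species = c("s1", "s1"), fate = "DISCARD",
                   weight_kg = c(0.4, 0.6))
  expect_equal(pool_discards_to_net(it, pool[0, ]), c(s1 = 1.0))

  # equal volumes leave subsample weights unscaled
  pool_eq <- transform(pool, total_volume_l = 20)
  expect_equal(pool_discards_to_net(none, pool_eq), c(maerl = 0.5))
  # total below the subsample volume is also unscaled (all was weighed)
  pool_lo <- transform(pool, total_volume_l = 10)
  expect_equal(pool_discards_to_net(none, pool_lo), c(maerl = 0.5))

  # mixed wall + pool over two species equals the manual sum
  it2 <- data.frame(item_id = c("a", "b", "c"),
                    wall_id = c("W1", "W1", "W2"),
                    species = c("maerl", "s1", "s1"), fate = "DISCARD",
                    weight_kg = c(0.2, 0.4, 0.6))
  got <- pool_discards_to_net(it2, pool)
  expect_equal(got[order(names(got))],
               c(maerl = 0.2 + 0.5 * 2, s1 = 1.0))
})

test_that("process_items resolves weights by rule and prices marketable items", {
  items <- tiny_items()
  out <- process_items(items, tiny_lw(), tiny_prices())
  # measured length: 0.01 * 25^3 / 1000 kg
  expect_equal(out$weight_kg[1], 0.15625)
  # class record contributes its upper bound
  expect_equal(out$weight_kg[2], 0.004 * 40^3.1 / 1000)
  # direct weight kept
  expect_equal(out$weight_kg[3], 0.3)
  # revenue = weight * mean price (17, 18.36 -> 17.68)
  expect_equal(out$revenue_eur[1], 0.15625 * 17.68)
  expect_equal(out$revenue_eur[2:3], c(0, 0))

  # missing price table with marketable items present
  expect_error(process_items(items, tiny_lw()), "price table required")

  # unknown species in the LW table
  bad <- items
  bad$species[2] <- "Unknownus fishus"
  expect_error(process_items(bad, tiny_lw(), tiny_prices()),
               "absent from the length-weight table")
})

test_that("wall_response aggregates to the hurdle dataset and keeps empty walls", {
  items <- process_items(tiny_items(), tiny_lw(), tiny_prices())
  hd <- wall_response(tiny_walls(), items, "discard_kg")
  expect_s3_class(hd, "hurdle_data")
  expect_equal(nrow(hd), 4L)
  expect_equal(hd$w, as.integer(hd$x > 0))
  # only W3 has a wall-attributable discard; the NET_LEVEL row is excluded
  expect_equal(sum(hd$w), 1L)
  expect_equal(hd$x[hd$wall_id == "W3"], 0.004 * 40^3.1 / 1000)

  rev <- wall_response(tiny_walls(), items, "revenue")
  expect_equal(rev$x[rev$wall_id == "W1"], 0.15625 * 17.68)
  expect_equal(sum(rev$w), 1L)
})

test_that("net totals combine wall items with the scaled pool fraction", {
  items <- process_items(tiny_items(), tiny_lw(), tiny_prices())
  nt <- net_discard_totals(tiny_walls(), items, tiny_pools())
  expect_equal(nrow(nt), 2L)
  n1 <- nt[nt$net_id == "N1", ]
  # pool: (0.5 + 0.2) * 40/20 = 1.4 kg; no wall discards on N1
  expect_equal(n1$total_kg, 1.4)
  expect_equal(n1$kg_per_wall, 0.7)
  n2 <- nt[nt$net_id == "N2", ]
  expect_equal(n2$total_kg, 0.004 * 40^3.1 / 1000)
})
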