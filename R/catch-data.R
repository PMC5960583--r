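## Catch data model, delimited-text I/O and deterministic processing rules.
##
## The statistical unit is the netting wall (a ~100 m trammel-net panel).
## Catch items are recorded per wall; small invertebrate/bed-forming bycatch
## that cannot be attributed to a wall is recorded once per net as a volume
## plus a 20-L weighed subsample.

#' Read the catch tables
#'
#' Reads and cross-validates the three core tables of a trammel-net catch
#' survey: netting walls, catch items and net-level pooled bycatch.
#'
#' Expected headers (comma-delimited, UTF-8, empty string = absent):
#' * `walls.csv`: `wall_id,trip_id,boat_id,net_id,wall_index,wall_type,depth_m,soak_h`
#' * `items.csv`: `item_id,wall_id,species,fate,length_cm,length_class_upper_cm,weight_kg,alive_on_arrival,commercial_category`
#' * `pools.csv`: `net_id,total_volume_l,subsample_volume_l,species,subsample_weight_kg`
#'
#' `wall_type` must be one of `PMF`, `MMF`, `MMF_GRECA`; `fate` one of
#' `MARKETABLE`, `DISCARD`.  An item `wall_id` must either resolve to a wall
#' or carry the `NET_LEVEL` marker (net-attributable fraction).
#'
#' @param walls_path,items_path,pools_path paths to the three files.
#'   `pools_path` may be `NULL` when no pooled fraction was recorded.
#' @return a list with elements `walls`, `items` and `pools` (data frames,
#'   row order preserved).
#' @export
read_catch_tables <- function(walls_path, items_path, pools_path = NULL) {
  walls <- read_delim_checked(walls_path,
    c("wall_id", "trip_id", "boat_id", "net_id", "wall_index", "wall_type",
      "depth_m", "soak_h"),
    types = c(wall_id = "character", trip_id = "character",
              boat_id = "character", net_id = "character",
              wall_index = "integer", wall_type = "character",
              depth_m = "numeric", soak_h = "numeric"))
  items <- read_delim_checked(items_path,
    c("item_id", "wall_id", "species", "fate", "length_cm",
      "length_class_upper_cm", "weight_kg", "alive_on_arrival",
      "commercial_category"),
    types = c(item_id = "character", wall_id = "character",
              species = "character", fate = "character",
              length_cm = "numeric", length_class_upper_cm = "numeric",
              weight_kg = "numeric", alive_on_arrival = "logical",
              commercial_category = "character"))
  pools <- if (is.null(pools_path)) empty_pools() else
    read_delim_checked(pools_path,
      c("net_id", "total_volume_l", "subsample_volume_l", "species",
        "subsample_weight_kg"),
      types = c(net_id = "character", total_volume_l = "numeric",
                subsample_volume_l = "numeric", species = "character",
                subsample_weight_kg = "numeric"))
  validate_catch_tables(walls, items, pools,
                        files = c(walls_path, items_path,
                                  pools_path %||% "<none>"))
  list(walls = walls, items = items, pools = pools)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_delim_checked <- function(path, cols, types = NULL) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  check_columns(df, cols, path)
  df <- df[cols]
  ## enforce the schema types (an all-empty csv column otherwise comes
  ## back logical)
  for (nm in names(types)) {
    df[[nm]] <- switch(types[[nm]],
                       numeric = as.numeric(df[[nm]]),
                       integer = as.integer(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       character = as.character(df[[nm]]))
  }
  df
}

empty_pools <- function() {
  data.frame(net_id = character(), total_volume_l = numeric(),
             subsample_volume_l = numeric(), species = character(),
             subsample_weight_kg = numeric(), stringsAsFactors = FALSE)
}

#' Validate a catch dataset
#'
#' Checks the structural invariants of the catch tables: enum fields, unique
#' wall ids, unique `wall_index` within a net, consistent trip/boat per net,
#' resolvable foreign keys and nonnegative measurements.  Errors name the
#' offending file and row.
#'
#' @param walls,items,pools data frames as returned by [read_catch_tables()].
#' @param files length-3 character vector used in error messages.
#' @return the (invisible) validated list.
#' @export
validate_catch_tables <- function(walls, items, pools,
                                  files = c("walls", "items", "pools")) {
  bad <- which(!walls$wall_type %in% WALL_TYPES)
  if (length(bad) > 0L)
    stopf("file '%s': row %d has unknown wall_type '%s'",
          files[1], bad[1], walls$wall_type[bad[1]])
  if (anyDuplicated(walls$wall_id))
    stopf("file '%s': duplicated wall_id '%s'", files[1],
          walls$wall_id[duplicated(walls$wall_id)][1])
  if (any(!is.finite(walls$wall_index) | walls$wall_index < 1 |
            walls$wall_index != round(walls$wall_index)))
    stopf("file '%s': wall_index must be an integer >= 1", files[1])
  if (any(walls$depth_m <= 0) || any(walls$soak_h <= 0))
    stopf("file '%s': depth_m and soak_h must be positive", files[1])
  for (net in unique(walls$net_id)) {
    sub <- walls[walls$net_id == net, ]
    if (anyDuplicated(sub$wall_index))
      stopf("file '%s': duplicated wall_index within net '%s'", files[1], net)
    if (length(unique(sub$trip_id)) != 1L ||
          length(unique(sub$boat_id)) != 1L)
      stopf("file '%s': net '%s' spans multiple trips or boats",
            files[1], net)
  }
  if (nrow(items) > 0L) {
    bad <- which(!items$fate %in% FATES)
    if (length(bad) > 0L)
      stopf("file '%s': row %d has unknown fate '%s'",
            files[2], bad[1], items$fate[bad[1]])
    dangling <- which(!(items$wall_id %in% walls$wall_id |
                          items$wall_id == NET_LEVEL))
    if (length(dangling) > 0L)
      stopf("file '%s': row %d references unknown wall_id '%s'",
            files[2], dangling[1], items$wall_id[dangling[1]])
    bad <- which(items$fate == "MARKETABLE" &
                   is.na(items$commercial_category))
    if (length(bad) > 0L)
      stopf("file '%s': row %d is MARKETABLE without a commercial_category",
            files[2], bad[1])
  }
  if (nrow(pools) > 0L) {
    if (any(pools$total_volume_l < 0) || any(pools$subsample_volume_l <= 0))
      stopf("file '%s': volumes must be nonnegative (subsample positive)",
            files[3])
    if (any(pools$subsample_weight_kg < 0))
      stopf("file '%s': subsample weights must be nonnegative", files[3])
    dangling <- which(!pools$net_id %in% walls$net_id)
    if (length(dangling) > 0L)
      stopf("file '%s': row %d references unknown net_id '%s'",
            files[3], dangling[1], pools$net_id[dangling[1]])
  }
  invisible(list(walls = walls, items = items, pools = pools))
}

#' Write the catch tables
#'
#' Inverse of [read_catch_tables()]; writes `walls.csv`, `items.csv`,
#' `pools.csv` and, when present in `x`, `prices.csv` and `lw_params.csv`.
#'
#' @param x a list with elements `walls`, `items`, `pools` and optionally
#'   `prices`, `lw` (e.g. the result of [simulate_catch()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_catch_tables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c(walls = "walls.csv", items = "items.csv", pools = "pools.csv",
            prices = "prices.csv", lw = "lw_params.csv")
  written <- character()
  for (nm in names(tabs)) {
    if (is.null(x[[nm]])) next
    path <- file.path(dir, tabs[[nm]])
    utils::write.csv(x[[nm]], path, row.names = FALSE, quote = FALSE,
                     na = "")
    written <- c(written, path)
  }
  invisible(written)
}

#' Read a first-sale price table
#'
#' One row per commercial category and fishing trip with the first-sale
#' price in Euros per kg.  The revenue rule uses the mean price of a
#' category over all trips.
#'
#' @param path path to `prices.csv`
#'   (`commercial_category,trip_id,price_eur_per_kg`).
#' @return validated data frame.
#' @export
read_price_table <- function(path) {
  df <- read_delim_checked(path,
    c("commercial_category", "trip_id", "price_eur_per_kg"))
  if (any(df$price_eur_per_kg < 0))
    stopf("file '%s': negative price", path)
  df
}

#' Read a length-weight coefficient table
#'
#' Allometric coefficients per species, `weight_g = a * length_cm^b`, with
#' the length type (total or carapace length) and a units tag declaring the
#' convention (only `g_cm` is currently accepted).
#'
#' @param path path to `lw_params.csv` (`species,a,b,length_type,units`).
#' @return validated data frame.
#' @export
read_lw_table <- function(path) {
  df <- read_delim_checked(path, c("species", "a", "b", "length_type",
                                   "units"))
  if (any(df$a <= 0)) stopf("file '%s': coefficient a must be positive", path)
  if (any(df$b < 1 | df$b > 4))
    stopf("file '%s': allometric exponent b outside [1, 4]", path)
  if (any(!df$units %in% "g_cm"))
    stopf("file '%s': unsupported length-weight units '%s'", path,
          setdiff(df$units, "g_cm")[1])
  if (anyDuplicated(df$species))
    stopf("file '%s': duplicated species", path)
  df
}

#' Convert length to weight
#'
#' Allometric length-weight conversion `a * length_cm^b / 1000`, with the
#' coefficients in the gram-centimeter convention and the result in kg.
#'
#' @param length_cm positive length (vectorised).
#' @param a,b allometric coefficients (`a` in g per cm^`b`).
#' @return weight in kg.
#' @examples
#' length_to_weight(10, a = 0.01, b = 3)  # 0.01 kg
#' @export
length_to_weight <- function(length_cm, a, b) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0))
    stopf("length_cm must be positive")
  if (any(a <= 0)) stopf("coefficient a must be positive")
  a * length_cm^b / 1000
}

#' Assign a length to its length class
#'
#' Field length classes are half-open intervals `(k*w, (k+1)*w]`; the class
#' is identified by its upper bound because downstream weight conversion
#' uses the class maximum.  A length on a boundary belongs to the class it
#' closes.  Width 10 cm is used for fish total length, 5 cm for lobster
#' carapace length.
#'
#' @param length_cm positive length (vectorised).
#' @param class_width_cm positive class width.
#' @return the class upper bound.
#' @examples
#' assign_length_class(23, 10)   # 30
#' assign_length_class(20, 10)   # 20
#' assign_length_class(7.1, 5)   # 10
#' @export
assign_length_class <- function(length_cm, class_width_cm) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0))
    stopf("length_cm must be positive")
  if (any(class_width_cm <= 0)) stopf("class_width_cm must be positive")
  ## small tolerance keeps exact boundaries in the class they close
  k <- ceiling(length_cm / class_width_cm - 1e-9)
  k * class_width_cm
}

#' Impute a missing length from conspecifics
#'
#' When an item has no size record, the mean size of sampled conspecifics is
#' used.  Measured lengths and class records (contributing their upper
#' bound) are pooled.
#'
#' @param items catch item data frame.
#' @param species species whose length is to be imputed.
#' @return imputed length in cm.
#' @export
impute_length <- function(items, species) {
  sub <- items[items$species == species, , drop = FALSE]
  lens <- ifelse(!is.na(sub$length_cm), sub$length_cm,
                 sub$length_class_upper_cm)
  lens <- lens[!is.na(lens)]
  if (length(lens) == 0L)
    stopf(paste0("no conspecific length available for species '%s'; ",
                 "drop or flag the item"), species)
  mean(lens)
}

#' Revenue of a single catch item
#'
#' First-sale revenue estimated as weight times the mean price of the item's
#' commercial category over all surveyed trips.
#'
#' @param weight_kg nonnegative weight.
#' @param category commercial category name.
#' @param prices price table (see [read_price_table()]).
#' @return revenue in Euros.
#' @export
item_revenue <- function(weight_kg, category, prices) {
  if (any(weight_kg < 0)) stopf("weight_kg must be nonnegative")
  p <- prices$price_eur_per_kg[prices$commercial_category == category]
  if (length(p) == 0L)
    stopf("commercial category '%s' absent from the price table", category)
  weight_kg * mean(p)
}

mean_price_table <- function(prices) {
  agg <- tapply(prices$price_eur_per_kg, prices$commercial_category, mean)
  data.frame(commercial_category = names(agg), mean_price = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Pool discards of one net
#'
#' Combines wall-attributable discard weights with the net-level subsampled
#' fraction.  Subsample weights are scaled linearly by
#' `total_volume_l / subsample_volume_l`; when the total volume does not
#' exceed the subsample volume the subsample weights are used unscaled
#' (the whole fraction was weighed).
#'
#' @param items processed discard items of a single net (must carry a
#'   resolved `weight_kg`; see [process_items()]).  Net-level marker rows
#'   are ignored (the pool records represent that fraction).
#' @param pools pool rows for the same net (possibly zero rows).
#' @return named numeric vector, species -> kg at net level.
#' @export
pool_discards_to_net <- function(items, pools) {
  if (nrow(pools) > 0L) {
    if (length(unique(pools$net_id)) > 1L)
      stopf("pool_discards_to_net expects a single net")
    if (any(pools$total_volume_l < 0) || any(pools$subsample_volume_l <= 0))
      stopf("negative or zero volumes in pool records")
  }
  out <- numeric(0)
  wall_items <- items[items$wall_id != NET_LEVEL &
                        items$fate == "DISCARD", , drop = FALSE]
  if (nrow(wall_items) > 0L) {
    if (any(is.na(wall_items$weight_kg)))
      stopf("items must carry resolved weights; run process_items() first")
    s <- tapply(wall_items$weight_kg, wall_items$species, sum)
    out <- stats::setNames(as.numeric(s), names(s))
  }
  if (nrow(pools) > 0L) {
    scale <- ifelse(pools$total_volume_l <= pools$subsample_volume_l,
                    1, pools$total_volume_l / pools$subsample_volume_l)
    w <- pools$subsample_weight_kg * scale
    for (i in seq_along(w)) {
      sp <- pools$species[i]
      out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + w[i]
    }
  }
  out
}

#' Resolve item weights and revenues
#'
#' Applies the deterministic processing rules to every catch item:
#' * a recorded weight is kept;
#' * else a measured length is converted through the species length-weight
#'   relationship;
#' * else a length-class record contributes its class maximum;
#' * else the mean size of sampled conspecifics is imputed and converted.
#'
#' Marketable items additionally receive a first-sale revenue (weight times
#' mean category price over trips).
#'
#' @param items catch item data frame.
#' @param lw length-weight table (see [read_lw_table()]).
#' @param prices price table, required when marketable items are present.
#' @param on_missing_length `"error"` (default) or `"drop"` for items of a
#'   species with no size record at all.
#' @return `items` with `weight_kg` filled and a `revenue_eur` column.
#' @export
process_items <- function(items, lw, prices = NULL,
                          on_missing_length = c("error", "drop")) {
  on_missing_length <- match.arg(on_missing_length)
  if (nrow(items) == 0L) {
    items$revenue_eur <- numeric(0)
    return(items)
  }
  need <- is.na(items$weight_kg)
  len <- ifelse(!is.na(items$length_cm), items$length_cm,
                items$length_class_upper_cm)
  no_size <- need & is.na(len)
  if (any(no_size)) {
    drop_rows <- logical(nrow(items))
    for (sp in unique(items$species[no_size])) {
      rows <- no_size & items$species == sp
      li <- tryCatch(impute_length(items, sp), error = function(e) NA_real_)
      if (is.na(li)) {
        if (on_missing_length == "error")
          stopf(paste0("no size record for species '%s' and no conspecific",
                       " to impute from"), sp)
        drop_rows <- drop_rows | rows
      } else {
        len[rows] <- li
      }
    }
    if (any(drop_rows)) {
      items <- items[!drop_rows, , drop = FALSE]
      len <- len[!drop_rows]
    }
    need <- is.na(items$weight_kg)
  }
  if (any(need)) {
    idx <- match(items$species[need], lw$species)
    if (anyNA(idx))
      stopf("species '%s' absent from the length-weight table",
            items$species[need][which(is.na(idx))[1]])
    items$weight_kg[need] <- length_to_weight(len[need], lw$a[idx],
                                              lw$b[idx])
  }
  items$revenue_eur <- 0
  mk <- items$fate == "MARKETABLE"
  if (any(mk)) {
    if (is.null(prices))
      stopf("price table required: marketable items are present")
    mp <- mean_price_table(prices)
    idx <- match(items$commercial_category[mk], mp$commercial_category)
    if (anyNA(idx))
      stopf("commercial category '%s' absent from the price table",
            items$commercial_category[mk][which(is.na(idx))[1]])
    items$revenue_eur[mk] <- items$weight_kg[mk] * mp$mean_price[idx]
  }
  items
}

#' Per-wall hurdle response
#'
#' Aggregates processed items to the netting-wall level and returns the
#' dataset the hurdle model consumes: the per-wall total (`x`), the
#' occurrence indicator (`w = 1` iff `x > 0`), the gear type and the
#' boat/net hierarchy.  Net-level marker items are excluded (they cannot be
#' attributed to a wall).
#'
#' @param walls wall table.
#' @param items processed items (see [process_items()]).
#' @param response `"revenue"` (Euros from marketable items) or
#'   `"discard_kg"` (kg from discarded items).
#' @return a `hurdle_data` data frame (see [hurdle_data()]).
#' @export
wall_response <- function(walls, items, response = c("revenue",
                                                     "discard_kg")) {
  response <- match.arg(response)
  items <- items[items$wall_id != NET_LEVEL, , drop = FALSE]
  if (response == "revenue") {
    items <- items[items$fate == "MARKETABLE", , drop = FALSE]
    val <- items$revenue_eur
  } else {
    items <- items[items$fate == "DISCARD", , drop = FALSE]
    val <- items$weight_kg
  }
  x <- stats::setNames(numeric(nrow(walls)), walls$wall_id)
  if (nrow(items) > 0L) {
    s <- tapply(val, items$wall_id, sum)
    x[names(s)] <- as.numeric(s)
  }
  hurdle_data(x = as.numeric(x), type = walls$wall_type,
              boat = walls$boat_id, net = walls$net_id,
              wall_id = walls$wall_id)
}

#' Net-level pooled discard totals
#'
#' Pools wall-attributable discards with the subsampled net-level fraction
#' for every net (see [pool_discards_to_net()]) and standardises by the
#' number of netting walls of the net.
#'
#' @param walls wall table.
#' @param items processed items.
#' @param pools pool table.
#' @return data frame with one row per net: `net_id`, `boat_id`,
#'   `wall_type` (NA for mixed nets), `n_walls`, `total_kg`,
#'   `kg_per_wall`.
#' @export
net_discard_totals <- function(walls, items, pools) {
  nets <- unique(walls$net_id)
  res <- lapply(nets, function(net) {
    wsub <- walls[walls$net_id == net, , drop = FALSE]
    isub <- items[items$wall_id %in% wsub$wall_id &
                    items$fate == "DISCARD", , drop = FALSE]
    psub <- pools[pools$net_id == net, , drop = FALSE]
    tot <- sum(pool_discards_to_net(isub, psub))
    types <- unique(wsub$wall_type)
    data.frame(net_id = net, boat_id = wsub$boat_id[1],
               wall_type = if (length(types) == 1L) types else NA_character_,
               n_walls = nrow(wsub), total_kg = tot,
               kg_per_wall = tot / nrow(wsub), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
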