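station_columns <- c("haul_id", "x_km", "y_km", "year", "survey",
                     "swept_area_km2", "species", "catch_kg")

#' Read a station-catch table from CSV
#'
#' Long format, one row per haul x species (zeros explicit). Invalid input
#' is rejected with the offending row numbers — never coerced.
#'
#' @param path CSV path with header
#'   `haul_id,x_km,y_km,year,survey,swept_area_km2,species,catch_kg`.
#' @return Data frame of class `sdfa_catch`.
#' @export
read_station_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(station_columns, names(tab))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  tab <- tab[, station_columns]
  for (col in c("x_km", "y_km", "year", "swept_area_km2", "catch_kg")) {
    if (!is.numeric(tab[[col]]))
      stop("non-numeric values in column ", col, " (rows ",
           paste(utils::head(which(is.na(suppressWarnings(
             as.numeric(tab[[col]])))), 5), collapse = ", "), ")")
  }
  bad <- which(tab$catch_kg < 0)
  if (length(bad))
    stop("negative catch on row(s) ", paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(tab$swept_area_km2 <= 0)
  if (length(bad))
    stop("non-positive swept area on row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  class(tab) <- c("sdfa_catch", "data.frame")
  tab
}

#' Write a station-catch table to CSV
#'
#' Lossless round-trip counterpart of [read_station_table()].
#'
#' @param table A catch table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_station_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, station_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter survey stations by explicit quality rules
#'
#' Total filtering: every input row ends up in either the kept or the
#' rejected table, with a per-rule count of removed hauls. A haul failing
#' any rule is removed in full (all its species rows). Supported rules:
#' `swept_area_min`, `swept_area_max` (km2), `year_min`, `year_max`, and
#' `require_finite` (drop hauls with non-finite coordinates, swept area or
#' catches).
#'
#' @param table A catch table.
#' @param rules Named list of rules; empty list keeps everything.
#' @return List: `kept`, `rejected` (both `sdfa_catch`), and `report`
#'   (data frame of rule, n_hauls_removed).
#' @export
filter_stations <- function(table, rules = list()) {
  known <- c("swept_area_min", "swept_area_max", "year_min", "year_max",
             "require_finite")
  unknown <- setdiff(names(rules), known)
  if (length(unknown))
    stop("unknown filtering rule(s): ", paste(unknown, collapse = ", "))
  bad_haul <- list()
  with_rule <- function(name, haul_ids)
    if (length(haul_ids)) bad_haul[[name]] <<- unique(haul_ids)
  if (!is.null(rules$swept_area_min))
    with_rule("swept_area_min",
              table$haul_id[table$swept_area_km2 < rules$swept_area_min])
  if (!is.null(rules$swept_area_max))
    with_rule("swept_area_max",
              table$haul_id[table$swept_area_km2 > rules$swept_area_max])
  if (!is.null(rules$year_min))
    with_rule("year_min", table$haul_id[table$year < rules$year_min])
  if (!is.null(rules$year_max))
    with_rule("year_max", table$haul_id[table$year > rules$year_max])
  if (isTRUE(rules$require_finite)) {
    ok <- is.finite(table$x_km) & is.finite(table$y_km) &
      is.finite(table$swept_area_km2) & is.finite(table$catch_kg)
    with_rule("require_finite", table$haul_id[!ok])
  }
  all_bad <- unique(unlist(bad_haul))
  drop <- table$haul_id %in% all_bad
  kept <- table[!drop, , drop = FALSE]
  rejected <- table[drop, , drop = FALSE]
  report <- data.frame(
    rule = names(bad_haul),
    n_hauls_removed = vapply(bad_haul, length, integer(1)),
    row.names = NULL)
  class(kept) <- class(rejected) <- c("sdfa_catch", "data.frame")
  list(kept = kept, rejected = rejected, report = report)
}

#' Allometric length-weight conversion
#'
#' The standard power law `W = a * L^b` used to convert sampled fish lengths
#' to biomass before size-class aggregation.
#'
#' @param length Length(s) in cm, `> 0`.
#' @param a,b Allometric coefficients, `> 0`.
#' @return Weight(s), in the units implied by `a` (conventionally grams).
#' @export
length_to_weight <- function(length, a, b) {
  stopifnot(a > 0, b > 0)
  if (any(length <= 0)) stop("non-positive length")
  a * length^b
}

#' Fit the allometric length-weight coefficients
#'
#' Log-log least squares of weight on length: recovers `(a, b)` of
#' `W = a * L^b` exactly on noiseless power-law samples.
#'
#' @param length,weight Paired positive samples.
#' @return List `a`, `b`.
#' @export
fit_length_weight <- function(length, weight) {
  stopifnot(length(length) == length(weight), all(length > 0),
            all(weight > 0))
  co <- coef(lm(log(weight) ~ log(length)))
  list(a = unname(exp(co[1])), b = unname(co[2]))
}

#' Aggregate length samples into juvenile/adult biomass
#'
#' Converts each sampled fish to weight via its species' allometric
#' coefficients (unless a `weight_g` column is present) and sums biomass per
#' haul x species x size class. A fish exactly at the cutoff counts as
#' adult. Biomass is conserved: juvenile + adult equals the total weight.
#'
#' @param samples Data frame with `species`, `length_cm`, optional
#'   `weight_g` and `haul_id` columns.
#' @param cutoffs Named vector: species -> cutoff length (cm), e.g. the
#'   minimum conservation reference size.
#' @param lw Named list: species -> `list(a =, b =)` allometric
#'   coefficients (needed only when `weight_g` is absent).
#' @return Data frame: `haul_id`, `species`, `size_class`
#'   (`"juvenile"`/`"adult"`), `biomass_g`.
#' @export
aggregate_size_classes <- function(samples, cutoffs, lw = NULL) {
  sp <- unique(samples$species)
  miss <- setdiff(sp, names(cutoffs))
  if (length(miss))
    stop("no size-class cutoff for species: ", paste(miss, collapse = ", "))
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  if (is.null(samples$weight_g)) {
    miss <- setdiff(sp, names(lw))
    if (length(miss))
      stop("no length-weight coefficients for species: ",
           paste(miss, collapse = ", "))
    samples$weight_g <- mapply(
      function(L, s) length_to_weight(L, lw[[s]]$a, lw[[s]]$b),
      samples$length_cm, samples$species)
  }
  if (is.null(samples$haul_id)) samples$haul_id <- 1L
  samples$size_class <- ifelse(samples$length_cm >= cutoffs[samples$species],
                               "adult", "juvenile")
  agg <- aggregate(weight_g ~ haul_id + species + size_class,
                   data = samples, FUN = sum)
  names(agg)[names(agg) == "weight_g"] <- "biomass_g"
  agg[order(agg$haul_id, agg$species, agg$size_class), , drop = FALSE]
}
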