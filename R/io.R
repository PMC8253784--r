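#' Write a weekly cube to a plain-text CSV
#'
#' Long-format CSV (time, year, week, lat, lon, value) with `#key=value`
#' metadata header lines carrying the variable tag, units and grid shape.
#' Masked cells are written as empty fields and restored as mask on read.
#'
#' @param cube a `weekly_cube`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "weekly_cube"))
  d <- dim(cube$values)
  hdr <- c(paste0("#tag=", cube$tag), paste0("#units=", cube$units),
           paste0("#n_time=", d[1]), paste0("#n_lat=", d[2]),
           paste0("#n_lon=", d[3]))
  v <- cube$values
  v[!cube$mask] <- NA_real_
  df <- data.frame(
    time = rep(seq_len(d[1]), times = d[2] * d[3]),
    year = rep(cube$year, times = d[2] * d[3]),
    week = rep(cube$week, times = d[2] * d[3]),
    lat = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    lon = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.numeric(v)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a weekly cube written by [write_cube()]
#'
#' Validates the time axis: it must be complete and strictly increasing
#' with uniform one-week spacing; missing weeks abort with an error that
#' names the gaps.
#'
#' @param path CSV file path.
#' @return a `weekly_cube`.
#' @export
read_cube <- function(path) {
  lines <- readLines(path, n = 20L)
  hdr_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (h in hdr_lines) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  for (key in c("tag", "units", "n_time", "n_lat", "n_lon")) {
    if (is.null(meta[[key]])) stop_arg("cube file is missing #", key, " header")
  }
  df <- utils::read.csv(path, comment.char = "#")
  nt <- as.integer(meta$n_time); nla <- as.integer(meta$n_lat)
  nlo <- as.integer(meta$n_lon)
  times <- sort(unique(df$time))
  gaps <- setdiff(seq_len(nt), times)
  if (length(gaps) || any(diff(times) != 1L)) {
    stop_arg("non-uniform time axis; missing week indices: ",
             paste(utils::head(gaps, 10), collapse = ", "))
  }
  if (nrow(df) != nt * nla * nlo) {
    stop_arg("cube file has ", nrow(df), " rows; expected ", nt * nla * nlo)
  }
  df <- df[order(df$lon, df$lat, df$time), ]
  v <- array(df$value, c(nt, nla, nlo))
  cal <- df[df$lat == 1 & df$lon == 1, c("time", "year", "week")]
  cal <- cal[order(cal$time), ]
  weekly_cube(v, cal$year, cal$week, mask = !is.na(v),
              tag = meta$tag, units = meta$units)
}

#' Write a climate index as a 2-column CSV
#'
#' Columns `iso_week_start_date` (first day of each composite, counted
#' from `origin`) and `value`.
#'
#' @param index a `climate_index`.
#' @param path output path.
#' @param origin date of the first composite (default "1982-01-01").
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(index, path, origin = as.Date("1982-01-01")) {
  stopifnot(inherits(index, "climate_index"))
  df <- data.frame(
    iso_week_start_date = origin + 7 * (index$times - 1),
    value = index$values
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a climate index CSV written by [write_index_csv()]
#'
#' @param path CSV path.
#' @return a `climate_index`.
#' @export
read_index_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(times = seq_len(nrow(df)), values = df$value),
            class = "climate_index")
}

#' Run the full synthetic pipeline
#'
#' Generates cubes, computes SMN/SMT, climatology extrema, VCI/TCI/VHI,
#' percent-area and event statistics, trends of the area series, and the
#' teleconnection summary; writes every product as CSV/JSON under
#' `out_dir` with a JSON run manifest (config, seed, clip counters,
#' product list).
#'
#' @param config a [synthetic_config()].
#' @param episodes list of [drought_episode()]s.
#' @param out_dir output directory (created if needed).
#' @param vhi_weight VCI weight a in the VHI (default 0.5).
#' @param smoother_window smoothing window in weeks (default 5).
#' @param n_surrogates surrogate pairs for the coherence mask (default 100).
#' @return invisibly, a list with the in-memory products and the manifest.
#' @export
run_pipeline <- function(config, episodes = list(), out_dir,
                         vhi_weight = 0.5, smoother_window = 5,
                         n_surrogates = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  stage <- "synthetic"
  result <- tryCatch({
    fields <- generate_fields(config, episodes)

    stage <- "indices"
    smn <- smooth_series(fields$ndvi, smoother_window)
    smt <- smooth_series(fields$bt, smoother_window)
    vci <- compute_vci(smn, climatology_extrema(smn))
    tci <- compute_tci(smt, climatology_extrema(smt))
    vhi <- compute_vhi(vci, tci, a = vhi_weight)

    stage <- "drought"
    bands <- condition_bands()$label
    area <- lapply(bands, function(b) percent_area(vhi, b))
    names(area) <- bands
    area_df <- area[[1]][c("time", "year", "week")]
    for (b in bands) area_df[[b]] <- area[[b]]$percent_area
    reg_vhi <- regional_mean(vhi)
    events <- detect_events(reg_vhi)
    stats_df <- do.call(rbind, lapply(bands, function(b) {
      cs <- category_stats(vhi, b)
      data.frame(band = b, mean_vhi = cs$mean_vhi,
                 duration_weeks = cs$duration_weeks)
    }))

    stage <- "trends"
    trend_df <- do.call(rbind, lapply(bands, function(b) {
      ts <- trend_summary(area_df[[b]])
      data.frame(band = b, ols_slope = ts$ols_slope,
                 sens_slope = ts$sens_slope, mk_p = ts$mk_p,
                 significant = ts$significant_5pct)
    }))

    stage <- "phenology"
    smn_clim <- vapply(1:52, function(w) {
      mean(regional_mean(smn)[smn$week == w], na.rm = TRUE)
    }, numeric(1))
    season <- detect_growing_season(smn_clim)

    stage <- "teleconnection"
    telecon <- teleconnection_summary(
      tci, fields$enso, weeks = season_weeks(season),
      n_surrogates = n_surrogates, seed = config$rng_seed
    )

    stage <- "write"
    write_cube(vhi, pth("vhi_cube.csv"))
    write_index_csv(fields$enso, pth("enso_index.csv"))
    utils::write.csv(area_df, pth("percent_area.csv"), row.names = FALSE)
    utils::write.csv(events, pth("drought_events.csv"), row.names = FALSE)
    utils::write.csv(stats_df, pth("category_stats.csv"), row.names = FALSE)
    utils::write.csv(trend_df, pth("area_trends.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(pixel = seq_along(telecon$pearson$r), r = telecon$pearson$r),
      pth("pearson_map.csv"), row.names = FALSE)

    products <- c("vhi_cube.csv", "enso_index.csv", "percent_area.csv",
                  "drought_events.csv", "category_stats.csv",
                  "area_trends.csv", "pearson_map.csv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("vhitools")),
      seed = config$rng_seed,
      config = unclass(config),
      n_episodes = length(episodes),
      ndvi_cells_clipped = fields$n_clipped,
      vci_cells_clipped = attr(vci, "n_clipped"),
      tci_cells_clipped = attr(tci, "n_clipped"),
      growing_season = unclass(season),
      dominant_phase_rad = telecon$dominant_phase,
      products = products
    )
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(vhi = vhi, smn = smn, smt = smt, vci = vci, tci = tci,
         enso = fields$enso, area = area_df, events = events,
         category_stats = stats_df, trends = trend_df, season = season,
         teleconnection = telecon, manifest = manifest)
  }, error = function(e) {
    stop_arg("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(result)
}
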