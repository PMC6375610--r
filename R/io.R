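# Event-history CSV schema: two linked tables.
#   individuals.csv: id, temperature_C, sex, egg_days, larval_days,
#                    pupal_days, death_age_d
#   fecundity.csv:   id, age_d, eggs   (one row per recorded female-day)
# Comma-separated, UTF-8, header row required, "." decimal.

.ind_cols <- c("id", "temperature_C", "sex", "egg_days", "larval_days",
               "pupal_days", "death_age_d")
.fec_cols <- c("id", "age_d", "eggs")

#' Write cohorts to event-history CSV files
#'
#' Serialises one or more cohorts to the two-file event-history schema
#' (individuals + daily fecundity), sorted canonically by id (and age), so
#' a read/write round trip is byte-identical. When a cohort carries its
#' generating [scenario_config()], a sidecar JSON with the config is
#' written next to the CSVs.
#'
#' @param cohorts a `demog_cohort` or list of them (one per temperature).
#' @param dir output directory (created if missing).
#' @param stem file-name stem (default `"cohort"`).
#' @return invisibly, the paths written (individuals, fecundity, configs).
#' @export
write_event_history <- function(cohorts, dir, stem = "cohort") {
  if (inherits(cohorts, "demog_cohort")) cohorts <- list(cohorts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ind <- do.call(rbind, lapply(cohorts, function(x) x$individuals))
  fec <- do.call(rbind, lapply(cohorts, function(x) x$fecundity))
  ind <- ind[order(ind$id), , drop = FALSE]
  fec <- fec[order(fec$id, fec$age_d), , drop = FALSE]
  p_ind <- file.path(dir, paste0(stem, "_individuals.csv"))
  p_fec <- file.path(dir, paste0(stem, "_fecundity.csv"))
  utils::write.csv(ind, p_ind, row.names = FALSE, quote = FALSE)
  utils::write.csv(fec, p_fec, row.names = FALSE, quote = FALSE)
  paths <- c(individuals = p_ind, fecundity = p_fec)
  cfgs <- Filter(Negate(is.null), lapply(cohorts, `[[`, "config"))
  if (length(cfgs)) {
    p_cfg <- file.path(dir, paste0(stem, "_config.json"))
    jsonlite::write_json(lapply(cfgs, unclass), p_cfg, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, config = p_cfg)
  }
  invisible(paths)
}

#' Read event-history CSV files into cohorts
#'
#' Parses and validates the two-file event-history schema, failing with
#' row-level messages on any violation: missing columns, duplicate ids,
#' fecundity rows referencing unknown ids, duplicate (id, age) pairs,
#' negative or non-integer values, or egg-laying ages outside an
#' individual's adult lifespan.
#'
#' @param individuals_path path to the individuals CSV.
#' @param fecundity_path path to the fecundity CSV.
#' @return named list of `demog_cohort` objects, one per temperature
#'   (names are the temperature values).
#' @export
read_event_history <- function(individuals_path, fecundity_path) {
  for (p in c(individuals_path, fecundity_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  ind <- utils::read.csv(individuals_path, stringsAsFactors = FALSE)
  fec <- utils::read.csv(fecundity_path, stringsAsFactors = FALSE)
  errs <- character(0)
  add <- function(...) errs <<- c(errs, sprintf(...))

  miss <- setdiff(.ind_cols, names(ind))
  if (length(miss)) add("individuals: missing columns %s",
                        paste(miss, collapse = ", "))
  miss <- setdiff(.fec_cols, names(fec))
  if (length(miss)) add("fecundity: missing columns %s",
                        paste(miss, collapse = ", "))
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  dup <- ind$id[duplicated(ind$id)]
  for (d in unique(dup)) add("individuals: duplicate id %s", d)
  if (!all(ind$sex %in% c("female", "male")))
    add("individuals: sex must be 'female' or 'male' (rows %s)",
        paste(which(!ind$sex %in% c("female", "male")), collapse = ", "))
  for (cl in c("egg_days", "larval_days", "pupal_days", "death_age_d")) {
    bad <- which(!is.finite(ind[[cl]]) | ind[[cl]] < 0 |
                   ind[[cl]] != round(ind[[cl]]))
    if (length(bad)) add("individuals: %s must be non-negative integers (rows %s)",
                         cl, paste(bad, collapse = ", "))
  }
  orphan <- setdiff(unique(fec$id), ind$id)
  for (o in orphan) add("fecundity: unknown id %s", o)
  dup2 <- duplicated(fec[c("id", "age_d")])
  if (any(dup2))
    for (j in which(dup2))
      add("fecundity: duplicate (id, age) pair (%s, %s)",
          fec$id[j], fec$age_d[j])
  bad <- which(!is.finite(fec$eggs) | fec$eggs < 0 |
                 fec$eggs != round(fec$eggs))
  if (length(bad)) add("fecundity: eggs must be non-negative integers (rows %s)",
                       paste(bad, collapse = ", "))
  bad <- which(!is.finite(fec$age_d) | fec$age_d < 0 |
                 fec$age_d != round(fec$age_d))
  if (length(bad)) add("fecundity: age_d must be non-negative integers (rows %s)",
                       paste(bad, collapse = ", "))
  if (!length(errs)) {
    m <- match(fec$id, ind$id)
    dev <- ind$egg_days[m] + ind$larval_days[m] + ind$pupal_days[m]
    bad <- which(fec$age_d < dev | fec$age_d >= ind$death_age_d[m])
    for (j in bad)
      add("fecundity: age %d outside adult lifespan of id %s",
          fec$age_d[j], fec$id[j])
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  split_temps <- split(seq_len(nrow(ind)), ind$temperature_C)
  out <- lapply(split_temps, function(rows) {
    sub_ind <- ind[rows, .ind_cols, drop = FALSE]
    sub_fec <- fec[fec$id %in% sub_ind$id, .fec_cols, drop = FALSE]
    rownames(sub_ind) <- rownames(sub_fec) <- NULL
    structure(list(individuals = sub_ind, fecundity = sub_fec,
                   config = NULL),
              class = "demog_cohort")
  })
  out
}

#' Write a life table (with age schedules) to CSV
#'
#' @param lt a [build_life_table()] result.
#' @param path output CSV path.
#' @param r intrinsic rate used for the reproductive-value column; solved
#'   from `lt` when `NULL` and reproduction exists.
#' @return invisibly, the augmented data frame written (age, lx, qx, mx,
#'   Vx, Ex).
#' @export
write_life_table <- function(lt, path, r = NULL) {
  lt <- .as_life_table(lt)
  Vx <- if (sum(lt$lx * lt$mx) > 0) reproductive_value(lt, r)$Vx else
    rep(NA_real_, nrow(lt))
  out <- data.frame(lt, Vx = Vx, Ex = expected_remaining_life(lt)$Ex)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
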