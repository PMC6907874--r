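# Dataset files: three comma-separated UTF-8 tables with header rows.
# trials.csv   one row per trial (participant, trial, block, permutation,
#              cost, q, hidden_jar, pink_side, n_samples, judgment, correct)
# samples.csv  one row per sampling choice (participant, trial, j, bead,
#              choice, dt); bead colors are coded P/B, booleans 0/1
# participants.csv  one row per participant (participant, aq, ...)

.trials_cols <- c("participant", "trial", "block", "permutation", "cost",
                  "q", "hidden_jar", "pink_side", "n_samples", "judgment",
                  "correct")
.samples_cols <- c("participant", "trial", "j", "bead", "choice", "dt")

#' Write a dataset to CSV files
#'
#' @param dataset list with `trials`, `samples`, `participants` data frames
#'   (e.g. from [simulate_population()]).
#' @param dir output directory (created if missing).
#' @param truth also write the ground-truth manifest (`manifest.csv`) when
#'   the dataset carries one.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(dataset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(dataset$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(dataset$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  if (truth && !is.null(dataset$manifest)) {
    write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read and validate a dataset
#'
#' Reads the CSV triplet written by [write_dataset()] and validates the
#' schema and integrity invariants: required columns present, sample
#' indices within the 20-draw cap, per-trial continue rows consistent with
#' `n_samples`, positive continue DTs, and referential integrity between
#' the three tables. Violations are reported with offending rows or ids.
#'
#' @param dir directory holding `trials.csv`, `samples.csv`,
#'   `participants.csv` (and optionally `manifest.csv`).
#' @param n_cap sampling cap, default 20.
#' @return list of class `"beads_dataset"`.
#' @export
read_dataset <- function(dir, n_cap = 20L) {
  paths <- file.path(dir, c("trials.csv", "samples.csv", "participants.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing dataset files: ",
                            paste(basename(missing), collapse = ", "))
  trials <- read.csv(paths[1], stringsAsFactors = FALSE)
  samples <- read.csv(paths[2], stringsAsFactors = FALSE)
  participants <- read.csv(paths[3], stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    read.csv(manifest_path, stringsAsFactors = FALSE)
  }
  dataset <- structure(list(trials = trials, samples = samples,
                            participants = participants, manifest = manifest),
                       class = "beads_dataset")
  validate_dataset(dataset, n_cap = n_cap)
  dataset
}

#' @rdname read_dataset
#' @param dataset a dataset list to validate in place.
#' @export
validate_dataset <- function(dataset, n_cap = 20L) {
  trials <- dataset$trials
  samples <- dataset$samples
  participants <- dataset$participants
  need_t <- setdiff(.trials_cols, names(trials))
  if (length(need_t)) stop("trials table lacks columns: ",
                           paste(need_t, collapse = ", "))
  need_s <- setdiff(.samples_cols, names(samples))
  if (length(need_s)) stop("samples table lacks columns: ",
                           paste(need_s, collapse = ", "))
  if (!"participant" %in% names(participants)) {
    stop("participants table lacks a `participant` column")
  }
  bad_j <- which(samples$j < 1 | samples$j > n_cap + 1L)
  if (length(bad_j)) stop("samples rows with j outside 1..", n_cap + 1L,
                          ": rows ", paste(head(bad_j, 5), collapse = ", "))
  bad_ns <- which(trials$n_samples < 0 | trials$n_samples > n_cap)
  if (length(bad_ns)) stop("trials rows with n_samples outside 0..", n_cap,
                           ": rows ", paste(head(bad_ns, 5), collapse = ", "))
  cont <- samples$choice == "continue"
  bad_dt <- which(cont & (!is.finite(samples$dt) | samples$dt <= 0))
  if (length(bad_dt)) stop("non-positive continue DTs at samples rows ",
                           paste(head(bad_dt, 5), collapse = ", "))
  orphan <- setdiff(unique(trials$participant), participants$participant)
  if (length(orphan)) stop("participants missing from participants table: ",
                           paste(orphan, collapse = ", "))
  orphan_s <- setdiff(unique(samples$participant), unique(trials$participant))
  if (length(orphan_s)) stop("samples reference unknown participants: ",
                             paste(orphan_s, collapse = ", "))
  # continue rows per trial must match n_samples
  key_s <- paste(samples$participant[cont], samples$trial[cont])
  counts <- table(key_s)
  key_t <- paste(trials$participant, trials$trial)
  got <- as.integer(counts[key_t])
  got[is.na(got)] <- 0L
  bad <- which(got != trials$n_samples)
  if (length(bad)) {
    stop("continue-row count disagrees with n_samples for trial keys: ",
         paste(head(key_t[bad], 5), collapse = "; "))
  }
  invisible(dataset)
}
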