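#' Default run configuration
#'
#' The resolved parameter set for a full pipeline run. Every detector and
#' normalization parameter is named here; [load_config()] validates user
#' files against this schema (unknown keys are rejected) and fills defaults.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    fps = 67,
    cardiac = list(
      min_ibi_s = 0.25,
      prominence_frac = 0.5,
      gap_factor = 2,
      search_window_s = 8,
      window_halfwidth_s = 0.5,
      baseline_window_s = 5,
      max_av_delay_s = 0.5
    ),
    locomotion = list(
      threshold = 0.05,
      min_gap_s = 0.1,
      envelope_s = 0.15,
      induction_window_s = 8
    ),
    dff = list(
      convention = "stim_onset",
      baseline_window_s = 2
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) {
    return(defaults)
  }
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0) {
    stop(
      "unknown config key(s): ",
      paste0(path, extra, collapse = ", "),
      call. = FALSE
    )
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(
        defaults[[nm]], user[[nm]],
        paste0(path, nm, ".")
      )
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' @param path Path to a YAML file (sections as in [default_config()]), or
#'   `NULL` for pure defaults.
#' @return The resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' Hash of a resolved configuration
#'
#' MD5 of the canonical YAML serialization; stamped into every output file a
#' pipeline run writes, for provenance.
#'
#' @param config A configuration list.
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

write_result_csv <- function(df, path, hash) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_md5: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline result CSV
#'
#' Reads a CSV written by [run_pipeline()] (skipping `#` provenance lines)
#' and returns it with the recorded config hash as attribute `config_md5`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_result_csv <- function(path) {
  first <- readLines(path, n = 1)
  hash <- if (startsWith(first, "# config_md5:")) {
    trimws(sub("# config_md5:", "", first))
  } else {
    NA_character_
  }
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "config_md5") <- hash
  df
}

#' Run the full analysis pipeline over a trial ledger
#'
#' Processes each ledger row according to its `kind`:
#' * `"heart"`: reads `atrium_csv` (and optionally `ventricle_csv`), runs
#'   beat detection, arrest metrics and AV delay; one row in
#'   `cardiac_results.csv`.
#' * `"tail"`: reads `tail_csv`, runs bout detection and trial
#'   classification; one row in `locomotion_results.csv`.
#'
#' Per-trial failures are isolated: the failing trial is recorded with
#' `status = "error"` and its message, and the remaining trials complete. The
#' resolved configuration (`config_used.yaml`), a library-version log and the
#' per-stage CSVs are written to `out_dir`; every CSV carries the config
#' hash. Given the same ledger, config and inputs, re-running produces
#' byte-identical result CSVs.
#'
#' @param ledger A data.frame with columns `larva_id`, `trial`, `kind`,
#'   `stim_onset_s`, and per-kind path columns (see above).
#' @param config A configuration list from [load_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the result data.frames.
#' @export
run_pipeline <- function(ledger, config = default_config(), out_dir) {
  stopifnot(is.data.frame(ledger))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  if (nrow(ledger) == 0) {
    warning("empty ledger: nothing to do")
    return(invisible(list()))
  }
  key <- paste(ledger$larva_id, ledger$trial, ledger$kind)
  if (anyDuplicated(key)) {
    stop("ledger keys (larva_id, trial, kind) must be unique", call. = FALSE)
  }

  cardiac <- NULL
  locomotion <- NULL
  errors <- 0L
  for (i in seq_len(nrow(ledger))) {
    row <- ledger[i, ]
    res <- tryCatch(
      {
        if (row$kind == "heart") {
          atr <- read_trace_csv(row$atrium_csv, label = "atrium")
          ven <- if (!is.null(row$ventricle_csv) && !is.na(row$ventricle_csv) &&
            nzchar(row$ventricle_csv)) {
            read_trace_csv(row$ventricle_csv, label = "ventricle")
          } else {
            NULL
          }
          m <- heart_trial_metrics(
            atr,
            stim_onset_s = row$stim_onset_s, ventricle = ven,
            min_ibi_s = config$cardiac$min_ibi_s,
            prominence_frac = config$cardiac$prominence_frac,
            gap_factor = config$cardiac$gap_factor,
            search_window_s = config$cardiac$search_window_s,
            max_av_delay_s = config$cardiac$max_av_delay_s
          )
          cbind(
            data.frame(
              larva_id = row$larva_id, trial = row$trial,
              status = "ok", message = ""
            ),
            m
          )
        } else if (row$kind == "tail") {
          tl <- read_trace_csv(row$tail_csv, label = "tail")
          bouts <- detect_bouts(tl,
            threshold = config$locomotion$threshold,
            min_gap_s = config$locomotion$min_gap_s,
            envelope_s = config$locomotion$envelope_s
          )
          cls <- classify_trial(bouts, row$stim_onset_s,
            induction_window_s = config$locomotion$induction_window_s
          )
          cbind(
            data.frame(
              larva_id = row$larva_id, trial = row$trial,
              status = "ok", message = ""
            ),
            as.data.frame(cls)
          )
        } else {
          stop("unknown trial kind: ", row$kind)
        }
      },
      error = function(e) {
        data.frame(
          larva_id = row$larva_id, trial = row$trial,
          status = "error", message = conditionMessage(e)
        )
      }
    )
    if (identical(res$status, "error")) errors <- errors + 1L
    if (row$kind == "heart") {
      cardiac <- merge_rows(cardiac, res)
    } else if (row$kind == "tail") {
      locomotion <- merge_rows(locomotion, res)
    }
  }

  out <- list()
  if (!is.null(cardiac)) {
    write_result_csv(cardiac, file.path(out_dir, "cardiac_results.csv"), hash)
    out$cardiac <- cardiac
  }
  if (!is.null(locomotion)) {
    write_result_csv(
      locomotion, file.path(out_dir, "locomotion_results.csv"), hash
    )
    out$locomotion <- locomotion
  }
  writeLines(yaml::as.yaml(config), file.path(out_dir, "config_used.yaml"))
  si <- utils::sessionInfo()
  writeLines(
    c(
      paste("R", paste(R.version$major, R.version$minor, sep = ".")),
      vapply(
        si$otherPkgs, function(p) paste(p$Package, p$Version),
        character(1)
      ),
      vapply(
        si$loadedOnly, function(p) paste(p$Package, p$Version),
        character(1)
      )
    ),
    file.path(out_dir, "library_versions.txt")
  )
  if (errors > 0) {
    warning(sprintf("%d trial(s) failed; see status column", errors))
  }
  invisible(out)
}

# rbind tolerating different column sets (error rows lack metric columns)
merge_rows <- function(acc, row) {
  if (is.null(acc)) {
    return(row)
  }
  all_cols <- union(names(acc), names(row))
  for (cn in setdiff(all_cols, names(acc))) acc[[cn]] <- NA
  for (cn in setdiff(all_cols, names(row))) row[[cn]] <- NA
  rbind(acc[all_cols], row[all_cols])
}
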