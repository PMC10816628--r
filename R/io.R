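# Format readers/writers and input validation for the pipeline surface.

#' Read a compound table (SMILES file)
#'
#' Tab- or comma-separated columns `id, smiles[, name, source]`, no header
#' required (a header line starting with "id" is skipped). Records whose
#' SMILES does not parse are rejected with a warning naming the id and line;
#' rejected rows are attached as `attr(x, "rejected")`.
#'
#' @param path file path.
#' @return data.frame: id, compound_id, smiles, name, source.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("^id[\t,]", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  parts <- strsplit(lines, "[\t,]")
  rows <- lapply(seq_along(parts), function(i) {
    p <- trimws(parts[[i]])
    if (length(p) < 2) return(NULL)
    data.frame(line = i, id = p[1], smiles = p[2],
               name = if (length(p) >= 3) p[3] else NA_character_,
               source = if (length(p) >= 4) toupper(p[4]) else "SYNTHETIC")
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no compound records in ", path)
  ok <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch({ parse_smiles(df$smiles[i]); TRUE },
             error = function(e) {
               warning("line ", df$line[i], ": unparseable SMILES for id '",
                       df$id[i], "': ", conditionMessage(e), call. = FALSE)
               FALSE
             })
  }, logical(1))
  if (anyDuplicated(df$id[ok]))
    stop("duplicate compound id(s): ",
         paste(unique(df$id[ok][duplicated(df$id[ok])]), collapse = ", "))
  out <- df[ok, c("id", "smiles", "name", "source"), drop = FALSE]
  out$compound_id <- out$id
  rownames(out) <- NULL
  attr(out, "rejected") <- df[!ok, , drop = FALSE]
  out
}

#' Read a docking-score table (CSV with compound_id, score)
#' @param path file path.
#' @return data.frame with at least `compound_id` and numeric `score`.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("compound_id", "score"), names(df))
  if (length(miss)) stop("score table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$score <- as.numeric(df$score)
  df
}

#' Read a viability plate table (CSV)
#' @param path file path.
#' @return data.frame accepted by [normalize_viability()].
#' @export
read_plates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("experiment", "replicate", "compound_id", "condition", "od"),
                  names(df))
  if (length(miss)) stop("plate table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write a data.frame as TSV
#' @param x data.frame. @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Performs per-file schema checks and returns diagnostics (never throws):
#' one row per problem with file, line (NA for file-level issues), level
#' ("error"/"warning") and message.
#'
#' @param paths named list with any of `smiles`, `scores`, `plates`.
#' @return data.frame of diagnostics (zero rows when everything is
#'   well-formed).
#' @export
validate_inputs <- function(paths) {
  diag <- list()
  note <- function(file, line, level, message) {
    diag[[length(diag) + 1L]] <<- data.frame(file = file, line = line,
                                             level = level, message = message)
  }
  if (!is.null(paths$smiles)) {
    if (!file.exists(paths$smiles)) {
      note(paths$smiles, NA, "error", "file does not exist")
    } else {
      withCallingHandlers(
        tryCatch(read_smiles_file(paths$smiles),
                 error = function(e) note(paths$smiles, NA, "error",
                                          conditionMessage(e))),
        warning = function(w) {
          note(paths$smiles, NA, "warning", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  }
  for (nm in c("scores", "plates")) {
    if (is.null(paths[[nm]])) next
    p <- paths[[nm]]
    if (!file.exists(p)) { note(p, NA, "error", "file does not exist"); next }
    reader <- if (nm == "scores") read_scores_csv else read_plates_csv
    tryCatch(reader(p), error = function(e) note(p, NA, "error",
                                                 conditionMessage(e)))
    if (nm == "plates" && file.exists(p)) {
      df <- tryCatch(utils::read.csv(p), error = function(e) NULL)
      if (!is.null(df) && "condition" %in% names(df) &&
          !"VEHICLE" %in% df$condition)
        note(p, NA, "error", "no VEHICLE records in plate table")
    }
  }
  if (length(diag) == 0)
    return(data.frame(file = character(0), line = integer(0),
                      level = character(0), message = character(0)))
  out <- do.call(rbind, diag)
  rownames(out) <- NULL
  out
}
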