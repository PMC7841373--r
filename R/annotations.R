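#' Ground-truth annotations for a session
#'
#' True event times, either produced by the simulator or read from an
#' annotation file: swimming-bout intervals, turn times with turn type,
#' and per-lap technique plus the five phase-begin events. All times are in
#' seconds from the start of the recording.
#'
#' @param bouts data.frame with columns `start`, `end`.
#' @param turns data.frame with columns `time`, `turn_type`
#'   (`"simple"`/`"tumble"`) and `bout` (1-based bout index); may have zero
#'   rows.
#' @param laps data.frame with one row per lap and columns `bout`, `lap`,
#'   `technique`, `turn_type`, `push_b`, `glid_b`, `stpr_b`, `swim_b`,
#'   `turn_b`, `lap_end`.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(bouts = data.frame(start = numeric(0),
                                            end = numeric(0)),
                         turns = data.frame(time = numeric(0),
                                            turn_type = character(0),
                                            bout = integer(0)),
                         laps = empty_truth_laps()) {
  gt <- structure(list(bouts = as.data.frame(bouts),
                       turns = as.data.frame(turns),
                       laps = as.data.frame(laps)),
                  class = "ground_truth")
  validate_ground_truth(gt)
  gt
}

empty_truth_laps <- function() {
  data.frame(bout = integer(0), lap = integer(0), technique = character(0),
             turn_type = character(0), push_b = numeric(0),
             glid_b = numeric(0), stpr_b = numeric(0), swim_b = numeric(0),
             turn_b = numeric(0), lap_end = numeric(0),
             stringsAsFactors = FALSE)
}

swim_techniques <- function() {
  c("front_crawl", "breaststroke", "butterfly", "backstroke")
}

validate_ground_truth <- function(gt) {
  b <- gt$bouts
  if (nrow(b) && any(b$end <= b$start)) {
    stop("ground_truth: every bout must satisfy start < end", call. = FALSE)
  }
  laps <- gt$laps
  if (nrow(laps)) {
    if (!all(laps$technique %in% swim_techniques())) {
      stop("ground_truth: unknown technique label", call. = FALSE)
    }
    ev <- as.matrix(laps[, c("push_b", "glid_b", "stpr_b", "swim_b",
                             "turn_b")])
    ok <- apply(ev, 1L, function(r) all(diff(r) > 0))
    if (!all(ok)) {
      stop("ground_truth: phase events out of order in lap(s) ",
           paste(which(!ok), collapse = ", "),
           " (need push_b < glid_b < stpr_b < swim_b < turn_b)",
           call. = FALSE)
    }
    for (i in seq_len(nrow(laps))) {
      bi <- laps$bout[i]
      if (bi >= 1L && bi <= nrow(b)) {
        if (laps$push_b[i] < b$start[bi] - 1e-9 ||
            laps$turn_b[i] > b$end[bi] + 1e-9) {
          stop("ground_truth: lap ", i, " events fall outside bout ", bi,
               call. = FALSE)
        }
      }
    }
  }
  invisible(gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d bout(s), %d turn(s), %d lap(s)\n",
              nrow(x$bouts), nrow(x$turns), nrow(x$laps)))
  invisible(x)
}

#' Write ground-truth annotations to JSON
#'
#' Versioned schema (`"swimseg-gt-1"`); round-trips losslessly through
#' [read_annotations()].
#'
#' @param gt a [ground_truth()] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_annotations <- function(gt, path) {
  validate_ground_truth(gt)
  obj <- list(schema = "swimseg-gt-1",
              bouts = gt$bouts, turns = gt$turns, laps = gt$laps)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read ground-truth annotations from JSON
#'
#' Ordering invariants (push_b < glid_b < stpr_b < swim_b < turn_b within
#' each lap, events inside their bout) are re-validated on read.
#'
#' @param path JSON file written by [write_annotations()].
#' @return a [ground_truth()] object.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "swimseg-gt-1")) {
    stop("read_annotations: unsupported schema: ",
         if (is.null(obj$schema)) "(none)" else obj$schema, call. = FALSE)
  }
  as_df <- function(x, template) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x)) {
      return(template)
    }
    as.data.frame(x)
  }
  ground_truth(bouts = as_df(obj$bouts,
                             data.frame(start = numeric(0),
                                        end = numeric(0))),
               turns = as_df(obj$turns,
                             data.frame(time = numeric(0),
                                        turn_type = character(0),
                                        bout = integer(0))),
               laps = as_df(obj$laps, empty_truth_laps()))
}
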