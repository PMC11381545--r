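#' @keywords internal
"_PACKAGE"

# Derive a reproducible per-stage seed from one global seed so that each
# simulation stage has its own RNG substream. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 104729
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2053 + h * 97 + 1)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Validate a longitudinal sample metadata table
#'
#' Checks the contract shared by every stage: columns `sample_id`,
#' `subject_id`, `visit_index` (integer-valued, ordered within subject, gaps
#' allowed), optional `group`; `sample_id` unique and
#' `(subject_id, visit_index)` unique.
#'
#' @param metadata data.frame of per-sample metadata.
#' @param samples optional character vector of sample ids that must all be
#'   covered by `metadata` (e.g. the columns of an abundance matrix).
#' @return the validated metadata, invisibly reordered by subject then visit.
#' @export
validate_metadata <- function(metadata, samples = NULL) {
  req <- c("sample_id", "subject_id", "visit_index")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0)
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  key <- paste(metadata$subject_id, metadata$visit_index)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, visit_index) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.numeric(metadata$visit_index) ||
      any(metadata$visit_index != round(metadata$visit_index)))
    stop("visit_index must be integer-valued")
  if (!is.null(samples)) {
    absent <- setdiff(samples, metadata$sample_id)
    if (length(absent) > 0)
      stop("sample(s) absent from metadata: ", paste(absent, collapse = ", "))
  }
  md <- metadata[order(metadata$subject_id, metadata$visit_index), , drop = FALSE]
  rownames(md) <- NULL
  invisible(md)
}

#' Enumerate consecutive same-subject visit pairs
#'
#' Adjacent *observed* visits of a subject define a pair, even across a
#' skipped visit index; subjects with a single visit contribute no pairs.
#'
#' @param metadata validated sample metadata.
#' @return data.frame with one row per pair: `subject_id`, `sample_t`,
#'   `sample_t1`, `visit_t`, `visit_t1`.
#' @export
consecutive_pairs <- function(metadata) {
  md <- validate_metadata(metadata)
  parts <- lapply(split(md, md$subject_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(subject_id = d$subject_id[-nrow(d)],
               sample_t   = d$sample_id[-nrow(d)],
               sample_t1  = d$sample_id[-1],
               visit_t    = d$visit_index[-nrow(d)],
               visit_t1   = d$visit_index[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(subject_id = character(), sample_t = character(),
                      sample_t1 = character(), visit_t = integer(),
                      visit_t1 = integer())
  rownames(out) <- NULL
  out
}
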