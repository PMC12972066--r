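#' Read and write the burst-table interchange format
#'
#' The interchange format is a pair of UTF-8 CSV files: a long counts table
#' with columns `burst_id, condition, bin_index, donor_counts, acceptor_counts`
#' (optional `true_pr` for synthetic data) and a per-burst metadata table with
#' columns `burst_id, bg_donor, bg_acceptor, bin_width_ms`. `bin_index` is
#' 0-based and must be contiguous within each burst.
#'
#' @param set A `burst_set`.
#' @param path Path of the counts CSV. The metadata table defaults to the same
#'   path with `_meta.csv` substituted for `.csv`.
#' @param meta_path Optional explicit metadata path.
#' @return `read_burst_table()` returns a `burst_set`; `write_burst_table()`
#'   returns `path` invisibly.
#' @export
write_burst_table <- function(set, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  rows <- lapply(set$bursts, function(b) {
    df <- data.frame(burst_id = b$id, condition = b$condition,
                     bin_index = seq_along(b$donor) - 1L,
                     donor_counts = as.integer(b$donor),
                     acceptor_counts = as.integer(b$acceptor))
    if (!is.null(b$ground_truth)) df$true_pr <- sprintf("%.17g", b$ground_truth)
    df
  })
  has_gt <- vapply(rows, function(d) "true_pr" %in% names(d), logical(1))
  if (any(has_gt) && !all(has_gt))
    rows <- lapply(rows, function(d) {
      if (!"true_pr" %in% names(d)) d$true_pr <- NA_character_
      d
    })
  counts <- do.call(rbind, rows)
  meta <- data.frame(
    burst_id = burst_ids(set),
    bg_donor = sprintf("%.17g", vapply(set$bursts, `[[`, numeric(1), "bg_donor")),
    bg_acceptor = sprintf("%.17g", vapply(set$bursts, `[[`, numeric(1), "bg_acceptor")),
    bin_width_ms = sprintf("%.17g", vapply(set$bursts, `[[`, numeric(1), "bin_width")))
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_meta_path <- function(path)
  if (grepl("\\.csv$", path)) sub("\\.csv$", "_meta.csv", path) else paste0(path, "_meta.csv")

#' @rdname write_burst_table
#' @export
read_burst_table <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  if (!file.exists(meta_path))
    stop("metadata file not found: ", meta_path, call. = FALSE)
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("burst_id", "condition", "bin_index", "donor_counts", "acceptor_counts")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  need_m <- c("burst_id", "bg_donor", "bg_acceptor", "bin_width_ms")
  miss <- setdiff(need_m, names(meta))
  if (length(miss))
    stop("metadata table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$burst_id))
    stop("duplicate burst_id in metadata table: ",
         paste(unique(meta$burst_id[duplicated(meta$burst_id)]), collapse = ", "),
         call. = FALSE)
  bad <- counts$donor_counts < 0 | counts$acceptor_counts < 0
  if (any(bad, na.rm = TRUE))
    stop("negative count at row ", which(bad)[1L],
         " (burst_id ", counts$burst_id[which(bad)[1L]], ")", call. = FALSE)
  ids <- unique(counts$burst_id)
  mrow <- match(ids, meta$burst_id)
  if (anyNA(mrow))
    stop("burst_id missing from metadata table: ",
         paste(ids[is.na(mrow)], collapse = ", "), call. = FALSE)
  idx <- split(seq_len(nrow(counts)), factor(counts$burst_id, levels = ids))
  bursts <- lapply(seq_along(ids), function(j) {
    i <- idx[[j]][order(counts$bin_index[idx[[j]]])]
    bi <- counts$bin_index[i]
    if (!identical(as.integer(bi), seq_along(bi) - 1L))
      stop("non-contiguous bin_index for burst_id ", ids[j], call. = FALSE)
    gt <- NULL
    if ("true_pr" %in% names(counts)) {
      g <- suppressWarnings(as.numeric(counts$true_pr[i]))
      if (!all(is.na(g))) gt <- g
    }
    m <- mrow[j]
    binned_burst(id = ids[j], donor = counts$donor_counts[i],
                 acceptor = counts$acceptor_counts[i],
                 bg_donor = meta$bg_donor[m], bg_acceptor = meta$bg_acceptor[m],
                 condition = counts$condition[i][1L],
                 bin_width = meta$bin_width_ms[m], ground_truth = gt)
  })
  burst_set(bursts, provenance = list(source = path))
}

#' Configuration-driven adapter for external burst deposits
#'
#' Best-effort ingestion of third-party burst tables (e.g. a public archive
#' deposit) whose column naming is not known in advance. `mapping` renames the
#' deposit's columns onto the interchange schema; the deposit must already be
#' a long per-bin CSV. Per-burst backgrounds are taken from the mapped columns
#' when present in the counts table, otherwise from `meta_path`.
#'
#' @param path Deposit counts CSV.
#' @param mapping Named character vector mapping interchange names
#'   (`burst_id`, `condition`, `bin_index`, `donor_counts`, `acceptor_counts`,
#'   optionally `bg_donor`, `bg_acceptor`, `bin_width_ms`) to deposit column
#'   names.
#' @param meta_path Optional companion metadata CSV (interchange schema).
#' @param condition Condition label to use when the deposit has no condition
#'   column.
#' @param bin_width_ms Bin width fallback, ms.
#' @return A `burst_set`.
#' @export
read_deposit_bursts <- function(path, mapping, meta_path = NULL,
                                condition = "DEPOSIT", bin_width_ms = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(mapping), names(raw))
  if (length(miss))
    stop("deposit is missing mapped column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  get <- function(key, default = NULL) {
    if (key %in% names(mapping)) raw[[mapping[[key]]]] else default
  }
  counts <- data.frame(
    burst_id = as.character(get("burst_id")),
    condition = get("condition", condition),
    bin_index = get("bin_index"),
    donor_counts = get("donor_counts"),
    acceptor_counts = get("acceptor_counts"))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp, default_meta_path(tmp))), add = TRUE)
  utils::write.csv(counts, tmp, row.names = FALSE, quote = FALSE)
  if (is.null(meta_path)) {
    ids <- unique(counts$burst_id)
    first <- match(ids, counts$burst_id)
    bgd <- get("bg_donor"); bga <- get("bg_acceptor"); bw <- get("bin_width_ms")
    meta <- data.frame(
      burst_id = ids,
      bg_donor = if (is.null(bgd)) 0 else bgd[first],
      bg_acceptor = if (is.null(bga)) 0 else bga[first],
      bin_width_ms = if (is.null(bw)) bin_width_ms else bw[first])
    meta_path <- default_meta_path(tmp)
    utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  }
  set <- read_burst_table(tmp, meta_path)
  set$provenance <- list(source = path, adapter = "read_deposit_bursts")
  set
}
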