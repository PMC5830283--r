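## Plain-text readers and writers for response matrices and item banks.

#' Read a response matrix from delimited text
#'
#' Comma-separated, header row of item ids, one row per respondent, blank cell
#' = missing. An optional leading `respondent` column becomes row names.
#' Ragged rows, non-integer cells and (when a bank is supplied) unknown item
#' ids or out-of-range categories are reported with their coordinates.
#'
#' @param path file path.
#' @param bank optional [ItemBank-class] to validate ids and category ranges
#'   against.
#' @return integer matrix, NA = missing.
#' @export
readResponseMatrix <- function(path, bank = NULL) {
  if (!file.exists(path)) stop("no such response file: ", path)
  if (!file.size(path) > 0) stop("empty response file: ", path)
  nf <- utils::count.fields(path, sep = ",", blank.lines.skip = TRUE,
                            quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": lines ",
         paste(utils::head(which(nf != nf[1L]), 5L), collapse = ", "))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!nrow(df)) stop("response file has a header but no rows: ", path)
  if (tolower(names(df)[1L]) %in% c("respondent", "id")) {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  } else rn <- NULL
  mat <- matrix(NA_integer_, nrow(df), ncol(df),
                dimnames = list(rn, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- trimws(df[[j]])
    blank <- v == "" | is.na(v)
    num <- suppressWarnings(as.numeric(v[!blank]))
    bad <- which(!blank)[is.na(num) | num != round(num)]
    if (length(bad))
      stop("non-integer cell(s) in column '", names(df)[j], "', row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    mat[!blank, j] <- as.integer(num)
  }
  if (!is.null(bank)) {
    ids <- itemIds(bank)
    unknown <- setdiff(colnames(mat), ids)
    if (length(unknown)) stop("unknown item id(s): ", paste(unknown, collapse = ", "))
    if (!identical(colnames(mat), ids)) mat <- mat[, ids, drop = FALSE]
    cats <- nCategories(bank)
    for (j in seq_len(ncol(mat))) {
      bad <- which(!is.na(mat[, j]) & (mat[, j] < 0L | mat[, j] > cats[j] - 1L))
      if (length(bad))
        stop("out-of-range cell(s) for item '", ids[j], "' (categories 0-",
             cats[j] - 1L, "): row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  mat
}

#' Write a response matrix as delimited text
#'
#' @param responses integer matrix, NA = missing (written blank).
#' @param path file path.
#' @export
writeResponseMatrix <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an item bank from structured text
#'
#' Key-value header lines (`link:`, `dimensions:`, `categories:`) followed by
#' one `item:` record per item: `item: id | label | a values | d values`,
#' pipe-separated, `#` comments ignored.
#'
#' @param path file path.
#' @return an [ItemBank-class].
#' @export
readItemBank <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  getKey <- function(key) {
    hit <- grep(paste0("^", key, ":"), ln, value = TRUE)
    if (!length(hit)) return(character())
    strsplit(trimws(sub(paste0("^", key, ":"), "", hit[1L])), "\\s+")[[1L]]
  }
  link <- getKey("link")
  if (!length(link)) stop("bank file missing 'link:' line")
  dims <- getKey("dimensions")
  cats <- getKey("categories")
  recs <- grep("^item:", ln, value = TRUE)
  if (!length(recs)) stop("bank file has no 'item:' records")
  items <- lapply(recs, function(r) {
    parts <- trimws(strsplit(sub("^item:", "", r), "|", fixed = TRUE)[[1L]])
    if (length(parts) != 4L)
      stop("malformed item record (need id | label | a | d): ", r)
    itemParameters(parts[1L], label = parts[2L],
                   a = as.numeric(strsplit(parts[3L], "\\s+")[[1L]]),
                   d = as.numeric(strsplit(parts[4L], "\\s+")[[1L]]),
                   link = link)
  })
  itemBank(items, dimensionNames = if (length(dims)) dims else NULL,
           categoryLabels = cats)
}

#' Write an item bank as structured text
#'
#' @param bank an [ItemBank-class].
#' @param path file path.
#' @export
writeItemBank <- function(bank, path) {
  fmt <- function(x) paste(format(x, trim = TRUE, digits = 10), collapse = " ")
  recs <- vapply(bank@items, function(it)
    paste("item:", it@itemId, "|", it@label, "|", fmt(it@a), "|", fmt(it@d)), "")
  writeLines(c(paste("link:", itemLink(bank)),
               paste("dimensions:", paste(bank@dimensionNames, collapse = " ")),
               if (length(bank@categoryLabels))
                 paste("categories:", paste(bank@categoryLabels, collapse = " ")),
               recs), path)
  invisible(path)
}

#' The packaged nine-item liver-stagnation / spleen-deficiency bank
#'
#' The two-factor probit-link item bank shipped with the package: items 1-5
#' load on the liver-stagnation factor, items 6-9 on the spleen-deficiency
#' factor, each with four severity categories. Item 9's first discrimination
#' is fixed at 0 by the simple-structure loading pattern.
#'
#' @param link override the stored link (`"probit"` default, `"logistic"`
#'   re-reads the same slopes on the logistic metric).
#' @return an [ItemBank-class].
#' @examples
#' bank <- lssdBank()
#' round(mdisc(bank), 2)
#' @export
lssdBank <- function(link = NULL) {
  path <- system.file("extdata", "lssd_bank.txt", package = "PatternSeverity",
                      mustWork = TRUE)
  bank <- readItemBank(path)
  if (!is.null(link) && link != itemLink(bank)) {
    items <- lapply(bank@items, function(it)
      itemParameters(it@itemId, a = it@a, d = it@d, link = link,
                     label = it@label))
    bank <- itemBank(items, loadingPattern = bank@loadingPattern,
                     dimensionNames = bank@dimensionNames,
                     categoryLabels = bank@categoryLabels)
  }
  bank
}
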