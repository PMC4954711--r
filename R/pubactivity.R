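#' Normalize a keyword
#'
#' Case-folds, trims, strips punctuation at the ends and collapses internal
#' whitespace. No stemming is applied: controlled vocabularies (MeSH,
#' subject categories, patent classes) would be merged unpredictably.
#'
#' @param x character vector of raw keywords
#' @return normalized character vector
#' @export
normalizeKeyword <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Parse publication or patent records
#'
#' Reads record exports in one of three dialects and returns a list of
#' records, each a list with elements \code{id}, \code{year},
#' \code{keywords} (normalized, distinct) and \code{dialect}.
#'
#' \describe{
#'   \item{medline}{tagged-field text: 4-character tag, \code{"- "},
#'     value; continuation lines start with whitespace; records separated
#'     by blank lines. The year is the first 4-digit number of the
#'     \code{DP} field; keywords come from the \code{MH} (MeSH) and
#'     \code{OT} tags, with MeSH major-topic stars and subheadings
#'     (\code{*Term/subheading}) stripped.}
#'   \item{wos}{tab-delimited export with a header; year column \code{PY};
#'     keywords from the \code{WC} (category) and \code{SC} (subject)
#'     columns, split on \code{";"}.}
#'   \item{patent}{tab-delimited with a header; year from the first of
#'     \code{PY}, \code{YEAR} or \code{ISD} present (for \code{ISD} dates
#'     the leading 4 digits); classifications from the \code{CPC} and
#'     \code{ICL} columns, split on \code{";"}.}
#' }
#'
#' Byte-identical records are removed, as are records whose keyword list is
#' empty after normalization. Records without a usable year are skipped and
#' their count reported via \code{message()}.
#'
#' @param path file path
#' @param dialect one of \code{"medline"}, \code{"wos"}, \code{"patent"}
#' @return list of record lists
#' @export
parseRecords <- function(path, dialect = c("medline", "wos", "patent")) {
  dialect <- match.arg(dialect)
  recs <- switch(dialect,
                 medline = .parseMedline(path),
                 wos = .parseTabular(path, "PY", c("WC", "SC"), "wos"),
                 patent = .parseTabular(path, c("PY", "YEAR", "ISD"),
                                        c("CPC", "ICL"), "patent"))
  noYear <- vapply(recs, function(r) is.na(r$year), logical(1))
  if (any(noYear))
    message(sum(noYear), " record(s) without a year skipped")
  recs <- recs[!noYear]
  recs <- lapply(recs, function(r) {
    kw <- unique(normalizeKeyword(r$keywords))
    r$keywords <- kw[nzchar(kw)]
    r
  })
  recs <- recs[vapply(recs, function(r) length(r$keywords) > 0, logical(1))]
  # deduplicate on full record content
  key <- vapply(recs, function(r)
    paste(r$id, r$year, paste(sort(r$keywords), collapse = "|")),
    character(1))
  recs[!duplicated(key)]
}

.parseMedline <- function(path) {
  lines <- readLines(path)
  # unfold continuation lines (leading whitespace)
  out <- list(); cur <- NULL
  flush <- function(cur) if (!is.null(cur) && length(cur$fields)) cur
  fields <- list(); tags <- character()
  recs <- list()
  lastTag <- NA_character_
  pushRec <- function() {
    if (!length(fields)) return()
    vals <- unlist(fields, use.names = FALSE)
    tg <- rep.int(tags, lengths(fields))
    dp <- vals[tg == "DP"]
    year <- if (length(dp)) {
      m <- regmatches(dp[1], regexpr("[0-9]{4}", dp[1]))
      if (length(m)) as.integer(m) else NA_integer_
    } else NA_integer_
    kw <- vals[tg %in% c("MH", "OT")]
    kw <- sub("^\\*", "", kw)          # MeSH major-topic marker
    kw <- sub("/.*$", "", kw)          # subheadings
    id <- vals[tg == "PMID"]
    recs[[length(recs) + 1L]] <<- list(
      id = if (length(id)) id[1] else paste0("rec", length(recs) + 1L),
      year = year, keywords = kw, dialect = "medline")
    fields <<- list(); tags <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { pushRec(); next }
    if (grepl("^\\s", ln)) {           # continuation of the previous field
      k <- length(fields)
      if (k) fields[[k]][length(fields[[k]])] <-
          paste(fields[[k]][length(fields[[k]])], trimws(ln))
      next
    }
    tag <- trimws(substr(ln, 1, 4))
    val <- sub("^.{4}-\\s?", "", ln)
    k <- length(fields)
    if (k && identical(tags[k], tag)) {
      fields[[k]] <- c(fields[[k]], val)
    } else {
      fields[[k + 1L]] <- val
      tags[k + 1L] <- tag
    }
  }
  pushRec()
  recs
}

.parseTabular <- function(path, yearCols, kwCols, dialect) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = TRUE)
  ycol <- intersect(yearCols, names(df))
  if (!length(ycol))
    stop("no year column (", paste(yearCols, collapse = "/"),
         ") found in ", path)
  yraw <- as.character(df[[ycol[1]]])
  year <- suppressWarnings(as.integer(substr(yraw, 1, 4)))
  present <- intersect(kwCols, names(df))
  if (!length(present))
    stop("no keyword column (", paste(kwCols, collapse = "/"),
         ") found in ", path)
  idcol <- intersect(c("UT", "ID", "PATNO", "PMID"), names(df))
  ids <- if (length(idcol)) as.character(df[[idcol[1]]]) else
    paste0("rec", seq_len(nrow(df)))
  lapply(seq_len(nrow(df)), function(i) {
    kw <- unlist(lapply(present, function(cl) {
      cell <- as.character(df[[cl]][i])
      if (is.na(cell)) character() else
        strsplit(cell, ";", fixed = TRUE)[[1]]
    }), use.names = FALSE)
    list(id = ids[i], year = year[i], keywords = kw, dialect = dialect)
  })
}

#' Count keyword appearances per year
#'
#' Builds the keywords-by-years matrix: entry (k, y) is the number of
#' records published in year y whose keyword list contains k — incidence,
#' so a keyword repeated within one record counts once. The year axis is
#' the contiguous span from the earliest to the latest observed year
#' (optionally padded to \code{yearRange}); years without records appear
#' as zero columns.
#'
#' @param records list of records from [parseRecords()] or
#'   [generateCorpus()]
#' @param yearRange optional integer range the axis is padded to
#' @return a [KeywordYearMatrix-class]
#' @export
countByYear <- function(records, yearRange = NULL) {
  if (!length(records)) stop("no records")
  years <- vapply(records, function(r) as.integer(r$year), integer(1))
  span <- if (is.null(yearRange)) range(years) else
    range(c(years, yearRange))
  axis <- seq.int(span[1], span[2])
  kws <- sort(unique(unlist(lapply(records, `[[`, "keywords"))))
  counts <- matrix(0L, length(kws), length(axis),
                   dimnames = list(kws, as.character(axis)))
  for (r in records) {
    col <- as.integer(r$year) - span[1] + 1L
    rows <- match(unique(r$keywords), kws)
    counts[rows, col] <- counts[rows, col] + 1L
  }
  new("KeywordYearMatrix", counts = counts, years = as.integer(axis))
}

#' Sample Pearson correlation coefficient
#'
#' Direct evaluation of
#' \deqn{r_{xy} = \sum_i (x_i - \bar x)(y_i - \bar y) /
#'   \sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}
#' reaching +1 for a perfectly increasing linear relationship and -1 for a
#' perfectly decreasing one. For a constant series the coefficient is
#' undefined and \code{NA} is returned (such pairs are excluded from
#' ranking).
#'
#' @param x,y numeric series of equal length >= 2
#' @return correlation in \[-1, 1\], or \code{NA} if undefined
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  r <- sum(dx * dy) / den
  min(1, max(-1, r))
}

#' Pairwise keyword co-occurrence counts
#'
#' Counts, for every unordered keyword pair, the number of records on
#' which both appear.
#'
#' @param records list of records
#' @return data.frame with columns \code{keywordA}, \code{keywordB}
#'   (lexicographically ordered within each row) and \code{coOccurrence}
#' @export
coOccurrenceCounts <- function(records) {
  pairs <- new.env(parent = emptyenv())
  for (r in records) {
    kw <- sort(unique(r$keywords))
    if (length(kw) < 2) next
    cmb <- utils::combn(kw, 2)
    for (q in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, q], cmb[2, q], sep = "\r")
      pairs[[key]] <- (if (is.null(pairs[[key]])) 0L else pairs[[key]]) + 1L
    }
  }
  keys <- ls(pairs)
  if (!length(keys))
    return(data.frame(keywordA = character(), keywordB = character(),
                      coOccurrence = integer()))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(keywordA = vapply(parts, `[`, character(1), 1),
             keywordB = vapply(parts, `[`, character(1), 2),
             coOccurrence = vapply(keys, function(k) pairs[[k]],
                                   integer(1)),
             row.names = NULL)
}

#' Correlations between co-occurring keyword pairs
#'
#' For every keyword pair that appeared at least once on the same record,
#' computes the Pearson correlation of the two yearly count series over
#' the whole year axis. Pairs with an undefined correlation (a constant
#' series) are dropped. Each unordered pair is stored once, with
#' \code{keywordA < keywordB} lexicographically.
#'
#' @param kym a [KeywordYearMatrix-class]
#' @param records the record list the matrix was built from (supplies the
#'   co-occurrence gate), or a data.frame from [coOccurrenceCounts()]
#' @return data.frame with columns \code{keywordA}, \code{keywordB},
#'   \code{r}, \code{coOccurrence}, \code{totalAppearances} (sum of the
#'   two keywords' overall counts)
#' @export
correlatePairs <- function(kym, records) {
  stopifnot(is(kym, "KeywordYearMatrix"))
  cooc <- if (is.data.frame(records)) records else
    coOccurrenceCounts(records)
  counts <- keywordCounts(kym)
  keep <- cooc$keywordA %in% rownames(counts) &
    cooc$keywordB %in% rownames(counts)
  cooc <- cooc[keep, , drop = FALSE]
  totals <- rowSums(counts)
  r <- vapply(seq_len(nrow(cooc)), function(i)
    pearsonCorrelation(counts[cooc$keywordA[i], ],
                       counts[cooc$keywordB[i], ]), numeric(1))
  out <- data.frame(keywordA = cooc$keywordA, keywordB = cooc$keywordB,
                    r = r, coOccurrence = cooc$coOccurrence,
                    totalAppearances = totals[cooc$keywordA] +
                      totals[cooc$keywordB],
                    row.names = NULL)
  out[!is.na(out$r), , drop = FALSE]
}

#' Rank keyword pairs and select the top-n keywords
#'
#' Orders the correlation table by descending correlation, then by
#' descending number of appearances, with a final lexicographic
#' tie-break on the keyword pair so the order is total and reruns are
#' identical. Keywords are collected in rank order until \code{n}
#' distinct ones are gathered.
#'
#' @param table data.frame from [correlatePairs()]
#' @param n number of keywords to select (e.g. 100 or 1000)
#' @param appearance which count backs the secondary sort key:
#'   \code{"coOccurrence"} (pair count, default) or
#'   \code{"totalAppearances"}
#' @return list with \code{keywords} (character vector, in selection
#'   order) and \code{ranking} (the sorted table)
#' @export
rankKeywords <- function(table, n,
                         appearance = c("coOccurrence",
                                        "totalAppearances")) {
  appearance <- match.arg(appearance)
  o <- order(-table$r, -table[[appearance]], table$keywordA,
             table$keywordB)
  ranked <- table[o, , drop = FALSE]
  sel <- character(0)
  for (i in seq_len(nrow(ranked))) {
    for (k in c(ranked$keywordA[i], ranked$keywordB[i])) {
      if (!(k %in% sel)) sel <- c(sel, k)
      if (length(sel) == n) break
    }
    if (length(sel) == n) break
  }
  if (length(sel) < n)
    warning("only ", length(sel), " distinct keywords available; ",
            "returning all of them")
  list(keywords = sel, ranking = ranked)
}

#' Build a yearly activity movie over a neuron-position layout
#'
#' Assigns each selected keyword a position sampled without replacement
#' from the supplied neuron-position set (seeded) and renders one frame
#' per year. In the default \code{"counts"} mode the intensity of a node
#' in year y is its yearly appearance count, min-max normalized over the
#' whole movie so the global minimum maps to 0 and the maximum to 1. In
#' \code{"correlation"} mode a sliding-window Pearson correlation is
#' computed for each selected co-occurring pair and painted onto both
#' endpoint nodes (a node takes the maximum over its pairs), then min-max
#' normalized the same way.
#'
#' @param kym a [KeywordYearMatrix-class]
#' @param keywords character vector of selected keywords (see
#'   [rankKeywords()])
#' @param positions matrix of available positions (at least as many rows
#'   as keywords)
#' @param seed RNG seed for the position assignment
#' @param mode \code{"counts"} or \code{"correlation"}
#' @param pairs for \code{"correlation"} mode, a data.frame of qualifying
#'   pairs (columns \code{keywordA}, \code{keywordB})
#' @param window sliding-window width in years for \code{"correlation"}
#'   mode
#' @return an [ActivityMovie-class]
#' @export
buildActivityMovie <- function(kym, keywords, positions, seed = 1L,
                               mode = c("counts", "correlation"),
                               pairs = NULL, window = 5) {
  mode <- match.arg(mode)
  stopifnot(is(kym, "KeywordYearMatrix"))
  positions <- as.matrix(positions)
  if (nrow(positions) < length(keywords))
    stop("fewer positions (", nrow(positions), ") than keywords (",
         length(keywords), ")")
  counts <- keywordCounts(kym)
  if (!all(keywords %in% rownames(counts)))
    stop("keywords missing from the count matrix")
  set.seed(seed)
  idx <- sample.int(nrow(positions), length(keywords))
  layout <- data.frame(node = keywords, x = positions[idx, 1],
                       y = positions[idx, 2], stringsAsFactors = FALSE)
  years <- yearAxis(kym)

  if (mode == "counts") {
    raw <- t(counts[keywords, , drop = FALSE])   # years x nodes
  } else {
    if (is.null(pairs)) stop("correlation mode requires 'pairs'")
    use <- pairs$keywordA %in% keywords & pairs$keywordB %in% keywords
    pairs <- pairs[use, , drop = FALSE]
    if (!nrow(pairs)) stop("no qualifying pairs among the keywords")
    raw <- matrix(0, length(years), length(keywords),
                  dimnames = list(NULL, keywords))
    half <- window - 1L
    for (p in seq_len(nrow(pairs))) {
      a <- counts[pairs$keywordA[p], ]
      b <- counts[pairs$keywordB[p], ]
      rc <- rep(0, length(years))
      for (y in seq_along(years)) {
        lo <- max(1L, y - half)
        if (y - lo + 1 >= 2) {
          v <- pearsonCorrelation(a[lo:y], b[lo:y])
          rc[y] <- if (is.na(v)) 0 else v
        }
      }
      raw[, pairs$keywordA[p]] <- pmax(raw[, pairs$keywordA[p]], rc)
      raw[, pairs$keywordB[p]] <- pmax(raw[, pairs$keywordB[p]], rc)
    }
  }

  rng <- range(raw)
  intensity <- if (diff(rng) == 0) matrix(0, nrow(raw), ncol(raw)) else
    (raw - rng[1]) / diff(rng)
  dimnames(intensity) <- list(NULL, keywords)
  new("ActivityMovie", intensity = intensity, layout = layout,
      frameLabels = as.character(years))
}

#' Write a correlation table as TSV
#'
#' @param table data.frame from [correlatePairs()]
#' @param path file path
#' @return \code{path}, invisibly
#' @export
writeCorrelationTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write an activity movie as a frames-by-nodes CSV
#'
#' First column is the frame label (year); remaining columns are the node
#' intensities, with node names in the header.
#'
#' @param movie an [ActivityMovie-class]
#' @param path file path
#' @return \code{path}, invisibly
#' @export
writeActivityMovie <- function(movie, path) {
  df <- data.frame(frame = movie@frameLabels,
                   intensityMatrix(movie), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert an activity movie to a fluorescence movie
#'
#' Wraps the intensity matrix and layout as a [FluorescenceMovie-class]
#' so publication activity can go through the same scattering and
#' comparison path as neural movies.
#'
#' @param movie an [ActivityMovie-class]
#' @param frameDt nominal frame interval carried over (ms)
#' @return a [FluorescenceMovie-class]
#' @export
asFluorescenceMovie <- function(movie, frameDt = 20) {
  stopifnot(is(movie, "ActivityMovie"))
  FluorescenceMovie(intensityMatrix(movie), frameDt = frameDt,
                    positions = as.matrix(nodeLayout(movie)[, c("x", "y")]))
}
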