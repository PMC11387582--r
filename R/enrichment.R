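#' Read a GMT gene-set file
#'
#' Parses the standard tab-separated GMT format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are collapsed; a line with fewer than 3 fields is an
#' error naming the line number.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_sets`: a tibble with `set`,
#'   `description`, and a `members` list-column of unique member IDs.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(tibble::tibble(set = character(0),
                                    description = character(0),
                                    members = list()),
                     class = c("gene_sets", class(tibble::tibble()))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop("malformed GMT line ", short[1], ": fewer than 3 fields")
  }
  tb <- tibble::tibble(
    set = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    members = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  if (anyDuplicated(tb$set)) stop("duplicate gene-set names in GMT")
  structure(tb, class = c("gene_sets", class(tb)))
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_sets` tibble (or any tibble with `set`,
#'   `description`, `members`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], sets$description[i], sets$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query list against a
#' background universe (here: all quantified proteins in the analyzed
#' matrix, not a genome-wide universe — CSF proteomics only ever sees a
#' biased detectable fraction). Sets are intersected with the background
#' before testing and filtered by size. For each set:
#' `fold_enrichment = (hits/|query|) / (|set|/|background|)` and the
#' p-value is the upper hypergeometric tail `P(X >= hits)`; FDR is
#' Benjamini-Hochberg across the tested sets.
#'
#' @param query Character vector of query IDs; must be a subset of
#'   `background`.
#' @param sets A `gene_sets` collection from [read_gmt()] (or a named
#'   list of member vectors).
#' @param background Character vector: the universe of testable IDs.
#' @param min_size,max_size Set-size bounds after background intersection
#'   (defaults 3 and 500).
#' @return Tibble sorted by p-value: `set`, `hits`, `query_size`,
#'   `set_size`, `background_size`, `fold_enrichment`, `p_value`, `fdr`.
#' @examples
#' sets <- tibble::tibble(set = "S", description = "",
#'                        members = list(paste0("g", 1:10)))
#' enrich(paste0("g", 1:10), sets, paste0("g", 1:100), min_size = 1)
#' @export
enrich <- function(query, sets, background, min_size = 3, max_size = 500) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(query) == 0) stop("empty query")
  if (length(background) == 0) stop("empty background")
  extra <- setdiff(query, background)
  if (length(extra) > 0) {
    stop("query IDs outside the background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  if (is.data.frame(sets)) {
    members <- stats::setNames(sets$members, sets$set)
  } else {
    members <- sets
  }
  n_bg <- length(background)
  n_q <- length(query)
  rows <- purrr::imap(members, function(mem, name) {
    in_bg <- intersect(unique(mem), background)
    k <- length(in_bg)
    if (k < min_size || k > max_size) return(NULL)
    hits <- length(intersect(query, in_bg))
    tibble::tibble(
      set = name, hits = hits, query_size = n_q, set_size = k,
      background_size = n_bg,
      fold_enrichment = (hits / n_q) / (k / n_bg),
      p_value = stats::phyper(hits - 1, k, n_bg - k, n_q,
                              lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(dplyr::mutate(tibble::tibble(
      set = character(0), hits = integer(0), query_size = integer(0),
      set_size = integer(0), background_size = integer(0),
      fold_enrichment = numeric(0), p_value = numeric(0)
    ), fdr = numeric(0)))
  }
  dplyr::mutate(out, fdr = bh_adjust(.data$p_value)) |>
    dplyr::arrange(.data$p_value, .data$set)
}
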