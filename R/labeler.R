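#' The literal GOF/LOF phrase list
#'
#' Twelve literal phrases: singular and plural of "gain of function",
#' "gain-of-function" and "gof", and the corresponding loss-of-function
#' forms. Matching is case-insensitive and token-bounded, so "golf" never
#' matches "gof" and "gain of functions" yields exactly one (plural) match.
#'
#' @return Tibble with columns `pattern` and `class`.
#' @export
gof_lof_patterns <- function() {
  base <- c("gain of function", "gain-of-function", "gof")
  loss <- c("loss of function", "loss-of-function", "lof")
  tibble::tibble(
    pattern = c(base, paste0(base, "s"), loss, paste0(loss, "s")),
    class = rep(c("GOF", "LOF"), each = 6L)
  )
}

# lowercase and normalize unicode dashes to ASCII hyphen
normalize_text <- function(x) {
  x <- tolower(x)
  gsub("[‐‑‒–—―−]", "-", x, perl = TRUE)
}

#' Match GOF/LOF phrases in a publication
#'
#' Scans the title and abstract of one publication for the literal phrase
#' list of [gof_lof_patterns()]. Text is lowercased and unicode dashes are
#' normalized to ASCII hyphens before matching; phrases only match at token
#' boundaries (delimited by non-alphanumeric characters), so substrings of
#' longer words do not count.
#'
#' @param title,abstract Character scalars (either may be empty).
#'
#' @return Tibble with one row per match: `field` ("title"/"abstract"),
#'   `pattern`, `class`, `start`, `end` (character positions in the
#'   normalized text). Zero rows when nothing matches.
#' @export
#' @examples
#' match_phrases(title = "A Gain-of-Function mutation in SCN2A")
match_phrases <- function(title = "", abstract = "") {
  pats <- gof_lof_patterns()
  scan_one <- function(text, field) {
    if (is.na(text) || !nzchar(text)) return(NULL)
    txt <- normalize_text(text)
    out <- purrr::pmap(pats, function(pattern, class) {
      # phrases contain only letters, spaces and hyphens, so they can be
      # dropped into a regex verbatim; require token boundaries both sides
      rx <- paste0("(?<![[:alnum:]])", pattern, "(?![[:alnum:]])")
      m <- gregexpr(rx, txt, perl = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      tibble::tibble(
        field = field, pattern = pattern, class = class,
        start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L
      )
    })
    dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(scan_one(title, "title"),
                          scan_one(abstract, "abstract"))
  if (nrow(res) == 0) {
    res <- tibble::tibble(field = character(), pattern = character(),
                          class = character(), start = integer(),
                          end = integer())
  }
  res
}

#' Decide a variant's GOF/LOF label from its publications
#'
#' Aggregates phrase matches over every associated publication: `GOF` if at
#' least one GOF-pattern match and no LOF-pattern match was found anywhere,
#' `LOF` symmetrically, `CONFLICT` when both classes matched (such variants
#' are excluded from training sets), and `UNLABELED` when nothing matched.
#' The decision is invariant to the order of the publications.
#'
#' @param variant_id Identifier carried through to the output.
#' @param docs Tibble of publications (`id`, `title`, `abstract`); may have
#'   zero rows.
#'
#' @return A list of class `label_decision` with fields `variant_id`,
#'   `verdict`, `n_gof`, `n_lof` and an `evidence` tibble
#'   (`publication_id`, `field`, `pattern`, `class`, `start`, `end`).
#' @export
decide_label <- function(variant_id, docs) {
  evidence <- if (is.null(docs) || nrow(docs) == 0) {
    tibble::tibble(publication_id = character(), field = character(),
                   pattern = character(), class = character(),
                   start = integer(), end = integer())
  } else {
    dplyr::bind_rows(purrr::pmap(
      docs[, c("id", "title", "abstract")],
      function(id, title, abstract) {
        m <- match_phrases(title, abstract)
        if (nrow(m) == 0) return(NULL)
        dplyr::mutate(m, publication_id = id, .before = 1)
      }
    ))
  }
  if (is.null(evidence) || nrow(evidence) == 0) {
    evidence <- tibble::tibble(publication_id = character(),
                               field = character(), pattern = character(),
                               class = character(), start = integer(),
                               end = integer())
  }
  n_gof <- sum(evidence$class == "GOF")
  n_lof <- sum(evidence$class == "LOF")
  verdict <- if (n_gof > 0 && n_lof > 0) "CONFLICT"
  else if (n_gof > 0) "GOF"
  else if (n_lof > 0) "LOF"
  else "UNLABELED"
  structure(
    list(variant_id = variant_id, verdict = verdict,
         n_gof = n_gof, n_lof = n_lof, evidence = evidence),
    class = "label_decision"
  )
}

#' Label many variants from a publication corpus
#'
#' @param variant_pubs Tibble linking variants to publications
#'   (`variant_id`, `publication_id`).
#' @param docs Publication tibble (`id`, `title`, `abstract`).
#'
#' @return Tibble with one row per variant: `variant_id`, `verdict`,
#'   `n_gof_hits`, `n_lof_hits`, `evidence` (JSON string).
#' @export
label_variants <- function(variant_pubs, docs) {
  dplyr::bind_rows(lapply(split(variant_pubs, variant_pubs$variant_id),
    function(vp) {
      d <- docs[docs$id %in% vp$publication_id, , drop = FALSE]
      dec <- decide_label(vp$variant_id[1], d)
      tibble::tibble(
        variant_id = dec$variant_id, verdict = dec$verdict,
        n_gof_hits = dec$n_gof, n_lof_hits = dec$n_lof,
        evidence = as.character(jsonlite::toJSON(dec$evidence))
      )
    }))
}

#' @method print label_decision
#' @export
print.label_decision <- function(x, ...) {
  cat(sprintf("<label_decision> %s: %s (%d GOF / %d LOF hits)\n",
              x$variant_id, x$verdict, x$n_gof, x$n_lof))
  invisible(x)
}
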