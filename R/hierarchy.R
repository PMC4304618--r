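#' Enumerate unordered sugar pairs
#'
#' All N(N-1)/2 unordered pairs, each once, in deterministic order (by
#' position in the supplied vector, which the callers pass in rank order).
#'
#' @param sugars character vector of sugar identifiers (>= 2, unique)
#' @return tibble with columns sugar_1, sugar_2
#' @examples
#' nrow(enumerate_pairs(letters[1:6]))  # 15
#' @export
enumerate_pairs <- function(sugars) {
  if (anyDuplicated(sugars)) stop("duplicate sugar names")
  if (length(sugars) < 2) stop("need at least 2 sugars")
  idx <- utils::combn(length(sugars), 2)
  tibble::tibble(sugar_1 = sugars[idx[1, ]], sugar_2 = sugars[idx[2, ]])
}

match_condition <- function(conditions, sugar_set) {
  hit <- vapply(conditions, function(cc) {
    pc <- parse_condition(cc)
    is.na(pc$camp) && setequal(names(pc$sugars), sugar_set)
  }, logical(1))
  conditions[hit]
}

#' Look up a condition summary by strain and sugar set
#'
#' Finds the summary row for a strain in the (non-cAMP) condition whose
#' sugar composition matches `sugar_set` exactly, regardless of
#' concentrations.
#' @param summaries condition summaries from [summarize_all()]
#' @param strain reporter strain
#' @param sugar_set character vector of sugar names
#' @return one summary row; error naming the missing condition otherwise
#' @export
lookup_summary <- function(summaries, strain, sugar_set) {
  conds <- match_condition(unique(summaries$condition), sugar_set)
  rows <- summaries[summaries$strain == strain &
                      summaries$condition %in% conds, ]
  if (nrow(rows) == 0) {
    stop("missing condition: ", strain, " on ",
         paste(sugar_set, collapse = "+"))
  }
  rows[1, ]
}

#' Rank sugars by the growth rate they support as sole carbon source
#'
#' Descending by mean mid-log growth rate of the cognate-reporter wells on
#' each sugar alone. Exact ties are broken alphabetically and flagged.
#'
#' @param summaries condition summaries (from [summarize_all()]) containing
#'   the cognate-alone condition of every sugar
#' @param ct constants table (maps promoters to cognate sugars)
#' @return list of class `sugar_ranking`: `sugars` (fastest first),
#'   `growth_rates`, `ties` (logical)
#' @export
rank_sugars <- function(summaries, ct = default_constants()) {
  p <- ct$promoters
  rates <- vapply(ct$sugars$name, function(s) {
    rep_strain <- p$name[p$cognate_sugar == s]
    lookup_summary(summaries, rep_strain, s)$mean_growth_rate
  }, numeric(1))
  ties <- anyDuplicated(rates) > 0
  ord <- order(-rates, names(rates))
  structure(
    list(sugars = names(rates)[ord], growth_rates = rates[ord], ties = ties),
    class = "sugar_ranking"
  )
}

#' Pairwise hierarchy matrix (row-normalized promoter activities)
#'
#' Entry (i, j) is the mid-log promoter activity of sugar i's reporter in
#' the mixture of its cognate sugar with sugar j, divided by its activity
#' on the cognate sugar alone; the diagonal is the cognate-alone condition
#' and is 1 by construction. Rows and columns are ordered by the sugar
#' ranking, so a strict hierarchy appears upper-triangular: full expression
#' above the diagonal, repression below. Negative normalized values are
#' clipped to 0 and flagged (attribute `clipped`).
#'
#' @param summaries condition summaries covering every pair and every
#'   cognate-alone condition
#' @param ranking a `sugar_ranking`
#' @param ct constants table
#' @param divide_by_growth alternative normalization dividing each
#'   condition's promoter activity by its growth rate before row
#'   normalization (off by default)
#' @return N x N matrix with sugar names as dimnames
#' @export
pair_matrix <- function(summaries, ranking, ct = default_constants(),
                        divide_by_growth = FALSE) {
  sugars <- ranking$sugars
  p <- ct$promoters
  n <- length(sugars)
  m <- matrix(NA_real_, n, n, dimnames = list(sugars, sugars))
  pa_of <- function(row) {
    if (divide_by_growth) {
      row$mean_promoter_activity / row$mean_growth_rate
    } else {
      row$mean_promoter_activity
    }
  }
  for (i in seq_len(n)) {
    rep_strain <- p$name[p$cognate_sugar == sugars[i]]
    own <- pa_of(lookup_summary(summaries, rep_strain, sugars[i]))
    for (j in seq_len(n)) {
      if (i == j) {
        m[i, j] <- 1
      } else {
        pair <- pa_of(lookup_summary(summaries, rep_strain,
                                     c(sugars[i], sugars[j])))
        m[i, j] <- pair / own
      }
    }
  }
  clipped <- m < 0
  m[clipped] <- 0
  attr(m, "clipped") <- which(clipped, arr.ind = TRUE)
  attr(m, "ranking") <- sugars
  m
}

#' Cross-activation matrix (reporters on sole non-cognate sugars)
#'
#' Entry (i, j) is the mid-log promoter activity of sugar i's reporter
#' growing on sugar j as sole carbon source, divided by its activity on its
#' cognate sugar; the diagonal is 1.
#'
#' @param summaries condition summaries covering all reporter x sole-sugar
#'   combinations
#' @param ranking a `sugar_ranking`
#' @param ct constants table
#' @return N x N matrix with sugar names as dimnames
#' @export
cross_matrix <- function(summaries, ranking, ct = default_constants()) {
  sugars <- ranking$sugars
  p <- ct$promoters
  n <- length(sugars)
  m <- matrix(NA_real_, n, n, dimnames = list(sugars, sugars))
  for (i in seq_len(n)) {
    rep_strain <- p$name[p$cognate_sugar == sugars[i]]
    own <- lookup_summary(summaries, rep_strain,
                          sugars[i])$mean_promoter_activity
    for (j in seq_len(n)) {
      m[i, j] <- lookup_summary(summaries, rep_strain,
                                sugars[j])$mean_promoter_activity / own
    }
  }
  m
}

#' Hierarchy dominance score of a rank-ordered pair matrix
#'
#' Fraction of unordered pairs (i < j in rank order) for which the
#' higher-ranked reporter is strictly more active with the lower sugar than
#' vice versa, i.e. `m[i, j] > m[j, i]`. Ties count as violations. A
#' perfectly hierarchical matrix scores 1.
#'
#' @param m rank-ordered hierarchy matrix
#' @return fraction in [0, 1]
#' @export
dominance_score <- function(m) {
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  wins <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    m[i, j] > m[j, i]
  }, logical(1))
  mean(wins)
}
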