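#' Build a drug/term vocabulary
#'
#' A vocabulary holds the three dictionaries the two surveillance domains
#' share: drug names (generic plus brand aliases), MedDRA-style event term
#' categories (each a named set of preferred terms, PTs), and the search-term
#' sets used to recognize abuse-related queries in the search-analytics
#' domain.
#'
#' @param drugs Tibble with columns `generic_name` (character) and
#'   `brand_names` (list of character vectors).
#' @param categories Tibble with columns `name`, `scope` (`"primary"` or
#'   `"secondary"`) and `pt_list` (list of character vectors of PTs).
#'   Exactly one category must have `scope = "primary"`.
#' @param query_terms Tibble with columns `name` (matching a category name)
#'   and `search_terms` (list of character vectors).
#' @return An object of class `vigicross_vocab`: a list of the three
#'   validated tibbles.
#' @seealso [default_vocab()], [map_pt()], [read_vocab()]
#' @export
vocabulary <- function(drugs, categories, query_terms) {
  drugs <- tibble::as_tibble(drugs)
  categories <- tibble::as_tibble(categories)
  query_terms <- tibble::as_tibble(query_terms)

  drugs$generic_name <- norm_string(drugs$generic_name)
  drugs$brand_names <- purrr::map(drugs$brand_names, norm_string)
  if (any(!nzchar(drugs$generic_name))) abort("Every drug needs a non-empty generic name.")
  if (anyDuplicated(drugs$generic_name)) abort("Duplicated generic drug names.")
  purrr::pwalk(drugs, function(generic_name, brand_names, ...) {
    if (anyDuplicated(brand_names)) {
      abort(sprintf("Duplicated brand names for '%s'.", generic_name))
    }
    if (generic_name %in% brand_names) {
      abort(sprintf("'%s' lists its generic name among its brand names.", generic_name))
    }
  })

  categories$name <- norm_string(categories$name)
  categories$pt_list <- purrr::map(categories$pt_list, norm_string)
  if (anyDuplicated(categories$name)) abort("Category names must be unique.")
  if (!all(categories$scope %in% c("primary", "secondary"))) {
    abort("Category scope must be 'primary' or 'secondary'.")
  }
  if (sum(categories$scope == "primary") != 1L) {
    abort("Exactly one category must have scope = 'primary'.")
  }
  if (any(lengths(categories$pt_list) == 0L)) abort("Every category needs a non-empty pt_list.")

  query_terms$name <- norm_string(query_terms$name)
  query_terms$search_terms <- purrr::map(query_terms$search_terms, norm_string)
  if (any(lengths(query_terms$search_terms) == 0L)) {
    abort("Every query term set needs at least one search term.")
  }
  unknown <- setdiff(query_terms$name, categories$name)
  if (length(unknown)) {
    abort(sprintf("Query term set(s) without a matching category: %s.",
                  paste(unknown, collapse = ", ")))
  }

  structure(
    list(drugs = drugs, categories = categories, query_terms = query_terms),
    class = "vigicross_vocab"
  )
}

#' @export
print.vigicross_vocab <- function(x, ...) {
  cat(sprintf(
    "<vigicross_vocab: %d drugs, %d term categories (primary: %s), %d query term sets>\n",
    nrow(x$drugs), nrow(x$categories),
    x$categories$name[x$categories$scope == "primary"], nrow(x$query_terms)
  ))
  invisible(x)
}

#' Default study vocabulary
#'
#' The packaged vocabulary covers four drugs -- the gabapentinoids pregabalin
#' (Lyrica) and gabapentin (Neurontin), the positive-control benzodiazepine
#' clonazepam (Klonopin) and the negative-control antiepileptic levetiracetam
#' (Keppra, with the variant spelling "kepra" kept as an alias) -- and five
#' abuse-related term categories with their search-domain counterparts
#' (`high` standing in for euphoria on the search side).
#'
#' The `tolerance`, `overdose` and `euphoria` categories enumerate their PTs
#' explicitly.  The two SMQ-based categories (`drug_abuse_and_dependence`,
#' the primary term, and `drug_withdrawal`, both "narrow scope") ship with
#' *placeholder* PT lists: narrow-scope SMQ membership is licensed MedDRA
#' content that cannot be redistributed, so users holding a MedDRA license
#' should override these two `pt_list`s (via [vocabulary()] or an edited
#' vocabulary file) with the licensed term sets.  Aggregate analyses driven
#' by published marginal counts (see [faers_marginals()]) do not depend on
#' the placeholder lists.
#'
#' @return A `vigicross_vocab` object.
#' @export
#' @examples
#' v <- default_vocab()
#' v$categories$name
default_vocab <- function() {
  drugs <- tibble::tibble(
    generic_name = c("pregabalin", "gabapentin", "clonazepam", "levetiracetam"),
    brand_names = list("lyrica", "neurontin", "klonopin", c("kepra", "keppra"))
  )
  categories <- tibble::tibble(
    name = c("drug_abuse_and_dependence", "drug_withdrawal", "overdose",
             "tolerance", "euphoria"),
    scope = c("primary", "secondary", "secondary", "secondary", "secondary"),
    pt_list = list(
      # placeholder for the narrow-scope SMQ "drug abuse and dependence"
      c("drug abuse", "drug dependence", "drug abuser", "substance abuse",
        "substance dependence", "drug use disorder", "substance use disorder",
        "dependence", "drug diversion"),
      # placeholder for the narrow-scope SMQ "drug withdrawal"
      c("drug withdrawal syndrome", "withdrawal syndrome",
        "drug withdrawal syndrome neonatal", "substance withdrawal syndrome",
        "rebound effect"),
      c("overdose", "intentional overdose"),
      c("drug tolerance", "drug tolerance increased"),
      c("euphoric mood", "feeling abnormal", "feeling drunk",
        "feeling of relaxation", "dizziness", "thinking abnormal",
        "hallucination", "inappropriate affect")
    )
  )
  query_terms <- tibble::tibble(
    name = c("drug_abuse_and_dependence", "drug_withdrawal", "overdose",
             "tolerance", "euphoria"),
    search_terms = list(c("abuse", "dependence"), "withdrawal", "overdose",
                        "tolerance", "high")
  )
  vocabulary(drugs, categories, query_terms)
}

#' Map an event preferred term to its categories
#'
#' Matching is exact-string after case-folding and whitespace normalization;
#' no stemming or fuzzy matching is attempted, since term categories are
#' defined by literal PT membership.  A PT may belong to several categories,
#' in which case all are returned.
#'
#' @param pt A single event preferred-term string.
#' @param categories A `vigicross_vocab`, or its `categories` tibble.
#' @return Character vector of category names containing `pt` (possibly
#'   empty), in vocabulary order.
#' @export
#' @examples
#' map_pt("Euphoric mood", default_vocab()) # "euphoria"
#' map_pt("myocardial infarction", default_vocab()) # character(0)
map_pt <- function(pt, categories) {
  if (inherits(categories, "vigicross_vocab")) categories <- categories$categories
  stopifnot(is.character(pt), length(pt) == 1L)
  key <- norm_string(pt)
  hit <- purrr::map_lgl(categories$pt_list, ~ key %in% .x)
  categories$name[hit]
}

#' Read or write a vocabulary file
#'
#' Vocabulary files are JSON or YAML (chosen by file extension) with
#' top-level keys `drugs`, `categories` and `query_term_sets`.  Each drug is
#' `{generic_name, brand_names}`, each category `{name, scope, pt_list}` and
#' each query term set `{name, search_terms}`.  The packaged default
#' (`system.file("extdata", "default_vocab.json", package = "vigicross")`)
#' reproduces [default_vocab()].
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_vocab()`: a `vigicross_vocab`.
#' @export
read_vocab <- function(path) {
  if (!file.exists(path)) abort(sprintf("Vocabulary file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("drugs", "categories", "query_term_sets")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("Vocabulary file must have top-level keys %s.",
                  paste(needed, collapse = ", ")))
  }
  vocabulary(
    drugs = tibble::tibble(
      generic_name = purrr::map_chr(raw$drugs, "generic_name"),
      brand_names = purrr::map(raw$drugs, ~ as.character(unlist(.x$brand_names)))
    ),
    categories = tibble::tibble(
      name = purrr::map_chr(raw$categories, "name"),
      scope = purrr::map_chr(raw$categories, "scope"),
      pt_list = purrr::map(raw$categories, ~ as.character(unlist(.x$pt_list)))
    ),
    query_terms = tibble::tibble(
      name = purrr::map_chr(raw$query_term_sets, "name"),
      search_terms = purrr::map(raw$query_term_sets, ~ as.character(unlist(.x$search_terms)))
    )
  )
}

#' @rdname read_vocab
#' @param vocab A `vigicross_vocab` object.
#' @return `write_vocab()`: `path`, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "vigicross_vocab"))
  payload <- list(
    drugs = purrr::pmap(vocab$drugs, function(generic_name, brand_names) {
      list(generic_name = generic_name, brand_names = as.list(brand_names))
    }),
    categories = purrr::pmap(vocab$categories, function(name, scope, pt_list) {
      list(name = name, scope = scope, pt_list = as.list(pt_list))
    }),
    query_term_sets = purrr::pmap(vocab$query_terms, function(name, search_terms) {
      list(name = name, search_terms = as.list(search_terms))
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

# resolve a drug argument to list(generic_name=, brand_names=) against a vocab
resolve_drug <- function(drug, vocab) {
  if (is.list(drug) && !is.null(drug$generic_name)) {
    return(list(generic_name = norm_string(drug$generic_name),
                brand_names = norm_string(drug$brand_names %||% character())))
  }
  stopifnot(is.character(drug), length(drug) == 1L)
  key <- norm_string(drug)
  i <- match(key, vocab$drugs$generic_name)
  if (is.na(i)) abort(sprintf("Unknown drug: '%s' is not in the vocabulary.", drug))
  list(generic_name = vocab$drugs$generic_name[i],
       brand_names = vocab$drugs$brand_names[[i]])
}

# resolve a category argument to list(name=, pt_list=) against a vocab
resolve_category <- function(category, vocab) {
  if (is.list(category) && !is.null(category$name) && !is.null(category$pt_list)) {
    return(list(name = norm_string(category$name),
                pt_list = norm_string(unlist(category$pt_list))))
  }
  stopifnot(is.character(category), length(category) == 1L)
  key <- norm_string(category)
  i <- match(key, vocab$categories$name)
  if (is.na(i)) abort(sprintf("Unknown term category: '%s'.", category))
  list(name = vocab$categories$name[i], pt_list = vocab$categories$pt_list[[i]])
}
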