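#' Life-stage labels used throughout the package
#'
#' The eight bumble bee life stages and castes that the default simulation
#' and the reporting tables use, in developmental order: egg, early (2nd-3rd)
#' instar larvae, late (4th) instar larvae, pupae, adult males, adult workers,
#' a diapausing queen and an egglaying queen.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' detox_stages()
detox_stages <- function() {
  c(
    "Egg", "Early instars", "Late instars", "Pupa",
    "Adult male", "Adult worker", "Diapausing queen", "Egglaying queen"
  )
}

#' Detoxification categories
#'
#' The four broad groupings used for gene-diversity tables:
#' oxidation-reduction enzymes, conjugation enzymes, hydrolytic enzymes, and
#' other stress-related proteins (ABC transporters, cadherins, heat shock
#' proteins, isomerases, lyases).
#'
#' @return Character vector of the four category ids.
#' @export
detox_categories <- function() {
  c("oxidation_reduction", "conjugation", "hydrolysis", "other")
}

#' Built-in keyword ontology for detoxification enzyme families
#'
#' An ordered rule table mapping keywords found in BLAST subject descriptions
#' to a detoxification category, an enzyme family, and (for cytochrome P450
#' and glutathione S-transferase subgroups of particular interest: CYP4, CYP6,
#' sigma-GST, epsilon-GST) a subfamily. Patterns are case-insensitive regular
#' expressions; the first matching rule wins, so subfamily rules precede their
#' family rule and longer keywords precede substrings they contain (e.g.
#' phosphodiesterase before esterase).
#'
#' @return A tibble with columns `pattern`, `category`, `family`, `subfamily`.
#' @seealso [read_ontology()] to load a user-supplied rule table.
#' @export
#' @examples
#' default_ontology()
default_ontology <- function() {
  rule <- function(pattern, category, family, subfamily = "") {
    tibble::tibble(
      pattern = pattern, category = category,
      family = family, subfamily = subfamily
    )
  }
  dplyr::bind_rows(
    ## subfamily rules first: first match wins
    rule("\\bCYP4\\w*", "oxidation_reduction", "cytochrome P450", "CYP4"),
    rule("\\bCYP6\\w*", "oxidation_reduction", "cytochrome P450", "CYP6"),
    rule(
      "sigma[- ]?(class )?(GST|glutathione)|glutathione S-transferase sigma",
      "conjugation", "glutathione S-transferase", "sigma-GST"
    ),
    rule(
      "epsilon[- ]?(class )?(GST|glutathione)|glutathione S-transferase epsilon",
      "conjugation", "glutathione S-transferase", "epsilon-GST"
    ),
    ## oxidation-reduction enzymes
    rule("aldehyde dehydrogenase", "oxidation_reduction", "aldehyde dehydrogenase"),
    rule("alcohol dehydrogenase", "oxidation_reduction", "alcohol dehydrogenase"),
    rule("catalase", "oxidation_reduction", "catalase"),
    rule("cytochrome P450|\\bCYP\\d", "oxidation_reduction", "cytochrome P450"),
    rule("dehalogenase", "oxidation_reduction", "dehalogenase"),
    rule("hydroxylase", "oxidation_reduction", "hydroxylase"),
    rule("oxidoreductase", "oxidation_reduction", "oxidoreductase"),
    rule("peroxidase", "oxidation_reduction", "peroxidase"),
    rule("superoxide dismutase", "oxidation_reduction", "superoxide dismutase"),
    rule("thioredoxin|glutaredoxin", "oxidation_reduction", "thioredoxin/glutaredoxin"),
    ## conjugation enzymes
    rule("acetyltransferase", "conjugation", "acetyltransferase"),
    rule("acyltransferase", "conjugation", "acyltransferase"),
    rule("CoA transferase|coenzyme A transferase", "conjugation", "CoA transferase"),
    rule("formyltransferase", "conjugation", "formyltransferase"),
    rule("glutathione S-transferase|\\bGST\\b", "conjugation", "glutathione S-transferase"),
    rule("UDP-glucuronosyltransferase", "conjugation", "UDP-glucuronosyltransferase"),
    rule("glycosyltransferase", "conjugation", "glycosyltransferase"),
    rule("methyltransferase", "conjugation", "methyltransferase"),
    rule("phosphotransferase", "conjugation", "phosphotransferase"),
    rule("sulfotransferase", "conjugation", "sulfotransferase"),
    rule("aminotransferase|transaminase", "conjugation", "transaminase"),
    ## hydrolytic enzymes (phosphodiesterase before the esterase rule)
    rule("phosphodiesterase", "hydrolysis", "phosphodiesterase"),
    rule(
      "acetylcholinesterase|carboxylesterase|\\besterase",
      "hydrolysis", "carboxylesterase/esterase"
    ),
    rule("alkaline phosphatase|acid phosphatase", "hydrolysis", "acid/alkaline phosphatase"),
    rule("amidase", "hydrolysis", "amidase"),
    rule("aminopeptidase", "hydrolysis", "aminopeptidase"),
    rule("amylase", "hydrolysis", "amylase"),
    rule("cyclohydrolase", "hydrolysis", "cyclohydrolase"),
    rule("glucosidase|glycosidase", "hydrolysis", "glycosidase"),
    rule("glucuronidase", "hydrolysis", "glucuronidase"),
    rule("glycosylase", "hydrolysis", "glycosylase"),
    rule("nitrilase", "hydrolysis", "nitrilase"),
    rule("phosphohydrolase", "hydrolysis", "phosphohydrolase"),
    ## other stress-related
    rule("ABC transporter|ATP-binding cassette", "other", "ABC transporter"),
    rule("cadherin", "other", "cadherin"),
    rule("heat shock protein|\\bHSP\\d", "other", "heat shock protein"),
    rule("isomerase", "other", "isomerase"),
    rule("lyase", "other", "lyase")
  )
}

#' Read a keyword ontology from TSV or YAML
#'
#' TSV files need columns `pattern`, `category`, `family` and optionally
#' `subfamily`; YAML files hold a list of rule mappings with the same keys.
#' Rule order in the file is preserved (first match wins). Every pattern is
#' compiled at load time so malformed regular expressions fail here, not
#' mid-pipeline.
#'
#' @param path Path to a `.tsv`/`.txt` or `.yaml`/`.yml` rule file.
#' @return A tibble with columns `pattern`, `category`, `family`, `subfamily`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) {
    stop("ontology file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    rules <- purrr::map_dfr(raw, function(r) {
      tibble::tibble(
        pattern = r$pattern %||% stop("ontology rule missing 'pattern'", call. = FALSE),
        category = r$category %||% stop("ontology rule missing 'category'", call. = FALSE),
        family = r$family %||% stop("ontology rule missing 'family'", call. = FALSE),
        subfamily = r$subfamily %||% ""
      )
    })
  } else {
    rules <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
    missing <- setdiff(c("pattern", "category", "family"), names(rules))
    if (length(missing) > 0) {
      stop("ontology file missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    if (!"subfamily" %in% names(rules)) rules$subfamily <- ""
    rules <- rules[, c("pattern", "category", "family", "subfamily")]
    rules$subfamily[is.na(rules$subfamily)] <- ""
  }
  validate_ontology(rules)
  rules
}

#' Write an ontology rule table to TSV
#'
#' @param ontology Rule tibble as returned by [default_ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  validate_ontology(ontology)
  readr::write_tsv(ontology, path)
  invisible(path)
}

validate_ontology <- function(rules) {
  if (nrow(rules) == 0) stop("ontology has no rules", call. = FALSE)
  bad_cat <- setdiff(unique(rules$category), detox_categories())
  if (length(bad_cat) > 0) {
    stop(
      "ontology uses unknown category: ", paste(bad_cat, collapse = ", "),
      " (expected one of ", paste(detox_categories(), collapse = ", "), ")",
      call. = FALSE
    )
  }
  for (p in rules$pattern) {
    ok <- tryCatch(
      {
        suppressWarnings(grepl(p, "x", ignore.case = TRUE, perl = TRUE))
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) stop("malformed ontology pattern: ", p, call. = FALSE)
  }
  invisible(rules)
}
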