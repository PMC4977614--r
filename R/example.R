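# A hand-built worked example family, used in the README and tests.

#' Worked example pedigree
#'
#' An eleven-member, three-generation high-risk family with six sequenced
#' members illustrating the five-level status model: two siblings affected
#' in their fifties (`CASE_DEFINITE`), their paternal aunt diagnosed at 83
#' (`CASE_POSSIBLE_PHENOCOPY` — at that age she may be a phenocopy), an
#' unaffected sister with recurrent polyps and three affected first-degree
#' relatives (`CONTROL_POSSIBLE_CARRIER`), and two married-in spouses with
#' clean family histories (`CONTROL_NONCARRIER`). The affected father of
#' the sibship was never sampled (`UNINFORMATIVE`).
#'
#' @return a [pedigree()]
#' @export
example_family <- function() {
  pedigree(
    id        = c("GF",  "GM",  "AUNT", "FATHER", "MOTHER",
                  "SIB1", "SIB2", "SIB3", "SP1",  "SP2",  "CHILD1"),
    father    = c(NA,    NA,    "GF",   "GF",     NA,
                  "FATHER", "FATHER", "FATHER", NA, NA,   "SP1"),
    mother    = c(NA,    NA,    "GM",   "GM",     NA,
                  "MOTHER", "MOTHER", "MOTHER", NA, NA,   "SIB1"),
    sex       = c("male", "female", "female", "male", "female",
                  "female", "male", "female", "male", "female", "male"),
    affected  = c(NA,    NA,    TRUE,   TRUE,     FALSE,
                  TRUE,  TRUE,  FALSE,  FALSE,  FALSE,  FALSE),
    status    = c(NA,    NA,    "CASE_POSSIBLE_PHENOCOPY", NA, NA,
                  "CASE_DEFINITE", "CASE_DEFINITE",
                  "CONTROL_POSSIBLE_CARRIER",
                  "CONTROL_NONCARRIER", "CONTROL_NONCARRIER", NA),
    sequenced = c(FALSE, FALSE, TRUE,   FALSE,    FALSE,
                  TRUE,  TRUE,  TRUE,   TRUE,   TRUE,   FALSE),
    birth_year = c(1920, 1922, 1930, 1932, 1935,
                   1958, 1960, 1962, 1956, 1959, 1985),
    diagnosis_year = c(NA, NA, 2013, 1990, NA,
                       2010, 2014, NA, NA, NA, NA)
  )
}
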