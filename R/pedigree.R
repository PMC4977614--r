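# Pedigree container, PED/status readers, validation, kinship.

#' Construct a pedigree
#'
#' A pedigree is a data.frame (class `pedigree`) with one row per family
#' member. Founders have `NA` parents. Every sequenced member must carry one
#' of the five analysis statuses in [STATUS_LEVELS]; members without a status
#' default to `UNINFORMATIVE`.
#'
#' @param id character member identifiers (unique).
#' @param father,mother parent identifiers, `NA` for founders.
#' @param sex "male", "female" or "unknown".
#' @param affected logical affection indicator (`NA` = unknown).
#' @param status analysis status, one of [STATUS_LEVELS]; `NA` allowed only
#'   for unsequenced members (coerced to `UNINFORMATIVE`).
#' @param sequenced logical: was this member sequenced?
#' @param birth_year,diagnosis_year optional integers used by the
#'   simulator's status-assignment rules.
#' @param family family identifier (single value or per member).
#'
#' @return validated object of class `pedigree` (a data.frame).
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = "unknown",
                     affected = NA, status = NA, sequenced = FALSE,
                     birth_year = NA, diagnosis_year = NA, family = "FAM1") {
  n <- length(id)
  ped <- data.frame(
    family = rep_len(as.character(family), n),
    id = as.character(id),
    father = rep_len(as.character(father), n),
    mother = rep_len(as.character(mother), n),
    sex = rep_len(as.character(sex), n),
    affected = rep_len(as.logical(affected), n),
    status = rep_len(as.character(status), n),
    sequenced = rep_len(as.logical(sequenced), n),
    birth_year = rep_len(suppressWarnings(as.integer(birth_year)), n),
    diagnosis_year = rep_len(suppressWarnings(as.integer(diagnosis_year)), n),
    stringsAsFactors = FALSE
  )
  ped$status[is.na(ped$status) & !ped$sequenced] <- "UNINFORMATIVE"
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
}

#' Validate a pedigree
#'
#' Checks parent links resolve, fathers are male and mothers female, no
#' member is its own ancestor, and every sequenced member has a status.
#'
#' @param ped a [pedigree()]
#' @return the pedigree, invisibly usable, with a `generation` column (0 for
#'   founders) appended.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("duplicate member ids")
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !ref %in% ped$id
    if (any(bad))
      stop("unknown ", col, " id: ", paste(unique(ref[bad]), collapse = ", "))
  }
  fa <- ped$sex[match(ped$father, ped$id)]
  if (any(!is.na(fa) & fa == "female")) stop("father listed as female")
  mo <- ped$sex[match(ped$mother, ped$id)]
  if (any(!is.na(mo) & mo == "male")) stop("mother listed as male")
  if (any(!ped$sex %in% c("male", "female", "unknown")))
    stop("sex must be male/female/unknown")

  # topological generation depth; failure to resolve => ancestry cycle
  gen <- rep(NA_integer_, nrow(ped))
  founder <- is.na(ped$father) & is.na(ped$mother)
  gen[founder] <- 0L
  repeat {
    pf <- gen[match(ped$father, ped$id)]
    pm <- gen[match(ped$mother, ped$id)]
    pf[is.na(ped$father)] <- -1L
    pm[is.na(ped$mother)] <- -1L
    newgen <- pmax(pf, pm) + 1L
    todo <- is.na(gen) & !is.na(newgen)
    if (!any(todo)) break
    gen[todo] <- newgen[todo]
  }
  if (anyNA(gen)) stop("cyclic ancestry detected involving: ",
                       paste(ped$id[is.na(gen)], collapse = ", "))
  ped$generation <- gen

  bad_status <- !is.na(ped$status) & !ped$status %in% STATUS_LEVELS
  if (any(bad_status))
    stop("unknown status: ",
         paste(unique(ped$status[bad_status]), collapse = ", "))
  if (any(ped$sequenced & is.na(ped$status)))
    stop("sequenced members must have an analysis status")
  ped
}

#' Read a 6-column PED file plus a status sidecar
#'
#' The PED file follows the conventional layout (family, individual, father,
#' mother, sex, phenotype) with `0` meaning "no parent" / "unknown". The
#' sidecar is a TSV with columns `individual_id` and `status`; members listed
#' there are taken as sequenced. Members absent from the sidecar get status
#' `UNINFORMATIVE` and `sequenced = FALSE`. Optional sidecar columns
#' `birth_year` and `diagnosis_year` are carried through.
#'
#' @param ped_path path to the PED file (whitespace-delimited).
#' @param status_path path to the status sidecar TSV; `NULL` for none.
#' @return a [pedigree()]
#' @export
read_pedigree <- function(ped_path, status_path = NULL) {
  tab <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6L) stop("PED file must have 6 columns: ", ped_path)
  names(tab)[1:6] <- c("family", "id", "father", "mother", "sex", "phenotype")
  tab$father[tab$father == "0"] <- NA
  tab$mother[tab$mother == "0"] <- NA
  sex <- c(`1` = "male", `2` = "female")[tab$sex]
  sex[is.na(sex)] <- "unknown"
  affected <- rep(NA, nrow(tab))
  affected[tab$phenotype == "2"] <- TRUE
  affected[tab$phenotype == "1"] <- FALSE

  status <- rep(NA_character_, nrow(tab))
  sequenced <- rep(FALSE, nrow(tab))
  by <- dy <- rep(NA_integer_, nrow(tab))
  if (!is.null(status_path)) {
    sc <- utils::read.table(status_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("individual_id", "status") %in% names(sc)))
      stop("status sidecar needs individual_id and status columns")
    unknown <- setdiff(sc$individual_id, tab$id)
    if (length(unknown) > 0L)
      stop("status sidecar references unknown individual(s): ",
           paste(unknown, collapse = ", "))
    idx <- match(sc$individual_id, tab$id)
    status[idx] <- sc$status
    sequenced[idx] <- TRUE
    if ("birth_year" %in% names(sc)) by[idx] <- as.integer(sc$birth_year)
    if ("diagnosis_year" %in% names(sc)) dy[idx] <- as.integer(sc$diagnosis_year)
  }
  pedigree(id = tab$id, father = tab$father, mother = tab$mother, sex = sex,
           affected = affected, status = status, sequenced = sequenced,
           birth_year = by, diagnosis_year = dy, family = tab$family)
}

#' Write a pedigree to PED + status sidecar
#'
#' @param ped a [pedigree()]
#' @param ped_path,status_path output file paths
#' @return invisibly, the two paths
#' @export
write_pedigree <- function(ped, ped_path, status_path) {
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  pheno <- ifelse(is.na(ped$affected), "0", ifelse(ped$affected, "2", "1"))
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sexcode, pheno)
  utils::write.table(out, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  seq_ped <- ped[ped$sequenced, , drop = FALSE]
  sc <- data.frame(individual_id = seq_ped$id, status = seq_ped$status,
                   birth_year = seq_ped$birth_year,
                   diagnosis_year = seq_ped$diagnosis_year)
  utils::write.table(sc, status_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ped_path, status_path))
}

#' Sequenced member ids of a pedigree
#' @param ped a [pedigree()]
#' @return character vector
#' @export
sequenced_members <- function(ped) ped$id[ped$sequenced]

#' Founder ids of a pedigree
#' @param ped a [pedigree()]
#' @return character vector
#' @export
founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Kinship coefficient between two pedigree members
#'
#' The kinship coefficient phi(i, j) is the probability that an allele drawn
#' at random from i and one drawn from j are identical by descent. Computed
#' by the standard recursion with founders taken as unrelated and
#' non-inbred: phi(i, i) = (1 + phi(father_i, mother_i)) / 2 and
#' phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2, recursing on the
#' member of the later generation (which therefore cannot be an ancestor of
#' the other).
#'
#' @param ped a [pedigree()]
#' @param i,j member ids
#' @return kinship coefficient in `[0, 0.5]` for non-inbred pairs
#' @export
kinship_coefficient <- function(ped, i, j) {
  kinship_matrix(ped, unique(c(i, j)))[i, j]
}

#' Pairwise kinship matrix
#'
#' @param ped a [pedigree()]
#' @param ids member ids to include (default: all members)
#' @return symmetric numeric matrix of kinship coefficients
#' @export
kinship_matrix <- function(ped, ids = ped$id) {
  unknown <- setdiff(ids, ped$id)
  if (length(unknown) > 0L)
    stop("unknown member(s): ", paste(unknown, collapse = ", "))
  ord <- ped$id[order(ped$generation)]
  n <- length(ord)
  fa <- match(ped$father[match(ord, ped$id)], ord)
  mo <- match(ped$mother[match(ord, ped$id)], ord)
  phi <- matrix(0, n, n, dimnames = list(ord, ord))
  for (a in seq_len(n)) {
    # self: 1/2 * (1 + phi(father, mother)); parents precede a in ord
    pm <- if (is.na(fa[a]) || is.na(mo[a])) 0 else phi[fa[a], mo[a]]
    phi[a, a] <- 0.5 * (1 + pm)
    if (a > 1L) {
      for (b in seq_len(a - 1L)) {
        # a is in the same or later generation than b: recurse through a's
        # parents (already filled rows)
        va <- 0
        if (!is.na(fa[a])) va <- va + phi[fa[a], b]
        if (!is.na(mo[a])) va <- va + phi[mo[a], b]
        phi[a, b] <- phi[b, a] <- 0.5 * va
      }
    }
  }
  phi[ids, ids, drop = FALSE]
}
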