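#' Construct a pedigree
#'
#' A pedigree is a set of dog records plus the litters they form. Each record
#' carries identity, parentage, sex, diagnosis status, age (at death if dead,
#' current age if alive) and a vital flag. Litter membership comes from an
#' explicit `litter_id` column rather than being inferred from shared parents,
#' because the same sire/dam pair can produce more than one litter.
#'
#' Parents that are referenced by other records but have no record of their
#' own are auto-created with unknown age and sex inferred from their parental
#' role; such dogs are unevaluable unless diagnosed.
#'
#' @param dogs data.frame with columns `id`, `sire`, `dam`, `sex`
#'   ("male"/"female"), `diagnosed` (logical), `age_years` (non-negative,
#'   `NA` if unknown), `alive` (logical), `litter_id` (token of the litter the
#'   dog was born into, `NA` for founders). `sire`, `dam` may be `NA`.
#' @param cutoff_age age in years at or beyond which an undiagnosed dog is
#'   considered unaffected (default 8.5).
#' @return an object of class `pedigree`: a list with elements `dogs`
#'   (validated data.frame) and `cutoff_age`.
#' @seealso [read_pedigree()], [assign_phenotypes()], [litters()]
#' @export
pedigree <- function(dogs, cutoff_age = 8.5) {
  stopifnot(is.data.frame(dogs), is.numeric(cutoff_age), cutoff_age > 0)
  required <- c("id", "sire", "dam", "sex", "diagnosed", "age_years", "alive")
  missing_cols <- setdiff(required, names(dogs))
  if (length(missing_cols) > 0L) {
    stop("pedigree table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"litter_id" %in% names(dogs)) dogs$litter_id <- NA_character_
  dogs <- as.data.frame(dogs, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam", "sex", "litter_id")) {
    dogs[[col]] <- as.character(dogs[[col]])
    dogs[[col]][!is.na(dogs[[col]]) & dogs[[col]] == ""] <- NA_character_
  }
  dogs$diagnosed <- as.logical(dogs$diagnosed)
  dogs$alive <- as.logical(dogs$alive)
  dogs$age_years <- as.numeric(dogs$age_years)

  dogs <- .autocreate_parents(dogs)
  .validate_dogs(dogs)
  structure(list(dogs = dogs, cutoff_age = cutoff_age), class = "pedigree")
}

# Parents referenced but absent get a structural record: sex from role,
# unknown age, undiagnosed.
.autocreate_parents <- function(dogs) {
  known <- dogs$id
  sires <- setdiff(stats::na.omit(unique(dogs$sire)), known)
  dams <- setdiff(stats::na.omit(unique(dogs$dam)), known)
  both <- intersect(sires, dams)
  if (length(both) > 0L) {
    stop("id(s) used both as sire and dam: ", paste(both, collapse = ", "))
  }
  if (length(sires) + length(dams) == 0L) return(dogs)
  extra <- data.frame(
    id = c(sires, dams),
    sire = NA_character_, dam = NA_character_,
    sex = c(rep("male", length(sires)), rep("female", length(dams))),
    diagnosed = FALSE, age_years = NA_real_, alive = FALSE,
    litter_id = NA_character_,
    stringsAsFactors = FALSE
  )
  if (nrow(extra) > 0L) dogs <- rbind(dogs, extra[names(dogs)])
  dogs
}

.validate_dogs <- function(dogs) {
  if (anyNA(dogs$id) || any(dogs$id == "")) stop("every dog needs a non-empty id")
  dup <- unique(dogs$id[duplicated(dogs$id)])
  if (length(dup) > 0L) stop("duplicate dog id(s): ", paste(dup, collapse = ", "))
  bad_sex <- dogs$id[!dogs$sex %in% c("male", "female")]
  if (length(bad_sex) > 0L) {
    stop("sex must be 'male' or 'female'; offending record(s): ",
         paste(bad_sex, collapse = ", "))
  }
  if (any(!is.na(dogs$age_years) & dogs$age_years < 0)) {
    stop("negative age_years for record(s): ",
         paste(dogs$id[!is.na(dogs$age_years) & dogs$age_years < 0], collapse = ", "))
  }
  sex_of <- stats::setNames(dogs$sex, dogs$id)
  sire_female <- dogs$sire[!is.na(dogs$sire) & sex_of[dogs$sire] != "male"]
  if (length(sire_female) > 0L) {
    stop("sire recorded as non-male: ", paste(unique(sire_female), collapse = ", "))
  }
  dam_male <- dogs$dam[!is.na(dogs$dam) & sex_of[dogs$dam] != "female"]
  if (length(dam_male) > 0L) {
    stop("dam recorded as non-female: ", paste(unique(dam_male), collapse = ", "))
  }
  # pups sharing a litter_id must share parents
  with_litter <- dogs[!is.na(dogs$litter_id), , drop = FALSE]
  if (nrow(with_litter) > 0L) {
    key <- paste(with_litter$litter_id,
                 ifelse(is.na(with_litter$sire), "", with_litter$sire),
                 ifelse(is.na(with_litter$dam), "", with_litter$dam), sep = "\r")
    n_keys <- tapply(key, with_litter$litter_id, function(k) length(unique(k)))
    bad <- names(n_keys)[n_keys > 1L]
    if (length(bad) > 0L) {
      stop("litter(s) with inconsistent parents: ", paste(bad, collapse = ", "))
    }
  }
  .check_acyclic(dogs)
  invisible(TRUE)
}

# Kahn's algorithm on parent -> child edges; leftovers indicate a cycle.
.check_acyclic <- function(dogs) {
  idx <- stats::setNames(seq_len(nrow(dogs)), dogs$id)
  n_parents <- (!is.na(dogs$sire)) + (!is.na(dogs$dam))
  children <- vector("list", nrow(dogs))
  for (i in seq_len(nrow(dogs))) {
    for (p in c(dogs$sire[i], dogs$dam[i])) {
      if (!is.na(p)) children[[idx[[p]]]] <- c(children[[idx[[p]]]], i)
    }
  }
  queue <- which(n_parents == 0L)
  seen <- 0L
  while (length(queue) > 0L) {
    i <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[i]]) {
      n_parents[ch] <- n_parents[ch] - 1L
      if (n_parents[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < nrow(dogs)) {
    stop("cyclic ancestry involving: ",
         paste(dogs$id[n_parents > 0L], collapse = ", "))
  }
  invisible(TRUE)
}

#' Litters of a pedigree
#'
#' @param ped a [pedigree()].
#' @return data.frame with one row per litter: `litter_id`, `sire`, `dam`,
#'   `n_pups`, and a list-column `pups` of pup ids.
#' @export
litters <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  dogs <- ped$dogs
  pups <- dogs[!is.na(dogs$litter_id), , drop = FALSE]
  if (nrow(pups) == 0L) {
    return(data.frame(litter_id = character(), sire = character(),
                      dam = character(), n_pups = integer(),
                      pups = I(list()), stringsAsFactors = FALSE))
  }
  ids <- unique(pups$litter_id)
  out <- data.frame(
    litter_id = ids,
    sire = vapply(ids, function(l) pups$sire[pups$litter_id == l][1L], character(1)),
    dam = vapply(ids, function(l) pups$dam[pups$litter_id == l][1L], character(1)),
    n_pups = vapply(ids, function(l) sum(pups$litter_id == l), integer(1)),
    stringsAsFactors = FALSE
  )
  out$pups <- I(lapply(ids, function(l) pups$id[pups$litter_id == l]))
  rownames(out) <- NULL
  out
}

#' Read a pedigree file
#'
#' The primary dialect is a headered CSV with columns
#' `id,sire,dam,sex,diagnosed,age_years,alive,litter_id` (UTF-8, comma
#' separated, "." decimal; empty field = unknown parent/litter/age). A
#' 6-column LINKAGE PED file (`family id sire dam sex affection`, with sex
#' coded 1 = male / 2 = female, affection 1 = unaffected / 2 = affected /
#' 0 = unknown, and "0" for an unknown parent) is accepted for
#' interoperability. PED carries no ages: affected dogs get `NA` age,
#' declared-unaffected dogs are assigned `age_years = cutoff_age` so that the
#' declared phenotype survives the age filter, and affection-0 dogs get `NA`
#' age (unevaluable). PED has no litter column, so one litter is formed per
#' (family, sire, dam) triple.
#'
#' @param path file path.
#' @param format "csv" or "ped"; default guessed from the file extension.
#' @param cutoff_age passed to [pedigree()].
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path, format = c("auto", "csv", "ped"),
                          cutoff_age = 8.5) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ped$", path, ignore.case = TRUE)) "ped" else "csv"
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character", sire = "character",
                                          dam = "character", sex = "character",
                                          litter_id = "character"))
    if (nrow(raw) == 0L) {
      raw <- data.frame(id = character(), sire = character(), dam = character(),
                        sex = character(), diagnosed = logical(),
                        age_years = numeric(), alive = logical(),
                        litter_id = character(), stringsAsFactors = FALSE)
    }
    return(pedigree(raw, cutoff_age = cutoff_age))
  }
  cols <- c("family", "id", "sire", "dam", "sex", "affection")
  raw <- utils::read.table(path, header = FALSE, col.names = cols,
                           colClasses = "character")
  if (!all(raw$sex %in% c("1", "2"))) stop("PED sex codes must be 1 or 2")
  if (!all(raw$affection %in% c("0", "1", "2"))) {
    stop("PED affection codes must be 0, 1 or 2")
  }
  sire <- ifelse(raw$sire == "0", NA_character_, raw$sire)
  dam <- ifelse(raw$dam == "0", NA_character_, raw$dam)
  has_parent <- !is.na(sire) | !is.na(dam)
  litter_id <- ifelse(has_parent,
                      paste(raw$family,
                            ifelse(is.na(sire), "0", sire),
                            ifelse(is.na(dam), "0", dam), sep = "_"),
                      NA_character_)
  dogs <- data.frame(
    id = raw$id, sire = sire, dam = dam,
    sex = ifelse(raw$sex == "1", "male", "female"),
    diagnosed = raw$affection == "2",
    age_years = ifelse(raw$affection == "1", cutoff_age, NA_real_),
    alive = FALSE, litter_id = litter_id,
    stringsAsFactors = FALSE
  )
  pedigree(dogs, cutoff_age = cutoff_age)
}

#' Write a pedigree
#'
#' `write_pedigree()` emits the package CSV dialect and round-trips all
#' fields. `write_linkage_ped()` exports the 6-column LINKAGE PED format;
#' ages and censoring are lost on export and the affection code is taken from
#' [assign_phenotypes()] (2 affected, 1 unaffected, 0 unevaluable).
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @param family family token for the PED export.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  utils::write.csv(ped$dogs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
write_linkage_ped <- function(ped, path, family = "F1") {
  stopifnot(inherits(ped, "pedigree"))
  phen <- assign_phenotypes(ped)
  code <- c(affected = "2", unaffected = "1", unevaluable = "0")
  dogs <- ped$dogs
  out <- data.frame(
    family = family, id = dogs$id,
    sire = ifelse(is.na(dogs$sire), "0", dogs$sire),
    dam = ifelse(is.na(dogs$dam), "0", dogs$dam),
    sex = ifelse(dogs$sex == "male", "1", "2"),
    affection = unname(code[phen[dogs$id]]),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  lit <- litters(x)
  cat(sprintf("<pedigree> %d dogs, %d litters (cutoff age %.1f y)\n",
              nrow(x$dogs), nrow(lit), x$cutoff_age))
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  phen <- assign_phenotypes(object)
  out <- list(
    n_dogs = nrow(object$dogs),
    n_litters = nrow(litters(object)),
    cutoff_age = object$cutoff_age,
    phenotypes = table(factor(phen, levels = c("affected", "unaffected",
                                               "unevaluable")))
  )
  class(out) <- "summary.pedigree"
  out
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat(sprintf("%d dogs in %d litters; cutoff %.1f y\n", x$n_dogs, x$n_litters,
              x$cutoff_age))
  print(x$phenotypes)
  invisible(x)
}
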