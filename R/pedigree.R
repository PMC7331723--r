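#' @include AllClasses.R AllGenerics.R
NULL

#' Build a nuclear family with a configurable consanguinity loop
#'
#' Constructs the pedigree of a sibship born to two parents related through
#' a consanguineous loop. The default, \code{loop = "first_cousins"},
#' builds the standard first-cousin graph: a shared ancestral founder
#' couple, their two sibling children who each marry an unrelated founder,
#' and the two resulting first cousins as the focal parents. With
#' \code{loop = "none"} the focal parents are unrelated founders (a plain
#' nuclear family). Children are created with affection status unknown
#' (0); status is assigned later from genotypes at a planted variant (see
#' \code{\link{plantVariant}}).
#'
#' @param n_children number of children of the focal couple.
#' @param loop \code{"first_cousins"} (default) or \code{"none"}.
#' @param child_sexes optional integer vector (1 = male, 2 = female) of
#'   length \code{n_children}; default alternates starting male.
#' @param fam family id string.
#' @return A \code{\link{Pedigree}}. Focal parents are always named
#'   \code{FA} (father) and \code{MO} (mother); children \code{C1..Cn}.
#'   For the first-cousin loop the shared great-grandparental founders (of
#'   the children) are \code{GG1}, \code{GG2}; their sibling children
#'   \code{S1}, \code{S2}; married-in founders \code{M1}, \code{M2}.
#' @examples
#' ped <- buildPedigree(n_children = 8)
#' nrow(pedTable(ped))  # 16 individuals
#' @export
buildPedigree <- function(n_children, loop = c("first_cousins", "none"),
                          child_sexes = NULL, fam = "FAM1") {
  loop <- match.arg(loop)
  if (n_children < 0) stop("n_children must be >= 0")
  if (is.null(child_sexes)) {
    child_sexes <- rep_len(c(1L, 2L), n_children)
  } else if (length(child_sexes) != n_children) {
    stop("child_sexes must have length n_children")
  }
  row <- function(id, fa, mo, sex, aff = 0L)
    data.frame(fam = fam, id = id, father = fa, mother = mo,
               sex = as.integer(sex), affected = as.integer(aff),
               stringsAsFactors = FALSE)
  if (loop == "first_cousins") {
    p <- rbind(
      row("GG1", "0", "0", 1L), row("GG2", "0", "0", 2L),
      row("S1",  "GG1", "GG2", 1L), row("S2", "GG1", "GG2", 2L),
      row("M1",  "0", "0", 2L), row("M2", "0", "0", 1L),
      row("FA",  "S1", "M1", 1L), row("MO", "M2", "S2", 2L))
  } else {
    p <- rbind(row("FA", "0", "0", 1L), row("MO", "0", "0", 2L))
  }
  if (n_children > 0) {
    kids <- do.call(rbind, lapply(seq_len(n_children), function(i)
      row(paste0("C", i), "FA", "MO", child_sexes[i])))
    p <- rbind(p, kids)
  }
  new("Pedigree", ped = p)
}

#' @rdname accessors
#' @export
setMethod("pedTable", "Pedigree", function(object) object@ped)

#' @rdname accessors
#' @export
setMethod("founders", "Pedigree", function(object) {
  p <- object@ped
  p$id[p$father == "0" & p$mother == "0"]
})

#' @rdname accessors
#' @export
setMethod("affectedIds", "Pedigree", function(object)
  object@ped$id[object@ped$affected == 2L])

#' @rdname accessors
#' @export
setMethod("unaffectedIds", "Pedigree", function(object)
  object@ped$id[object@ped$affected == 1L])

#' @rdname accessors
#' @export
setMethod("sampleIds", "Pedigree", function(object) object@ped$id)

setMethod("show", "Pedigree", function(object) {
  p <- object@ped
  nf <- length(founders(object))
  cat(sprintf("Pedigree: %d individuals (%d founders), %d affected / %d unaffected / %d unknown\n",
              nrow(p), nf, sum(p$affected == 2L), sum(p$affected == 1L),
              sum(p$affected == 0L)))
})

# children of pedigree ids in topological (parents-first) order
.nonfounders_toposorted <- function(ped) {
  p <- ped@ped
  done <- founders(ped)
  todo <- setdiff(p$id, done)
  out <- character(0)
  while (length(todo)) {
    ready <- todo[p$father[match(todo, p$id)] %in% done &
                  p$mother[match(todo, p$id)] %in% done]
    if (!length(ready)) stop("pedigree contains a cycle")
    out <- c(out, ready)
    done <- c(done, ready)
    todo <- setdiff(todo, ready)
  }
  out
}

#' Assign affection status on a pedigree
#'
#' @param ped a \code{\link{Pedigree}}.
#' @param affected character vector of affected ids; all other individuals
#'   with an entry in \code{known} are marked unaffected.
#' @param known character vector of ids with known status (default: all).
#' @return an updated \code{Pedigree}.
#' @export
setAffected <- function(ped, affected, known = pedTable(ped)$id) {
  p <- ped@ped
  stopifnot(all(affected %in% p$id), all(known %in% p$id))
  p$affected <- ifelse(p$id %in% affected, 2L,
                       ifelse(p$id %in% known, 1L, 0L))
  new("Pedigree", ped = p)
}

#' Read / write 6-column PED files
#'
#' Whitespace-delimited, columns: family, individual, father, mother,
#' sex (1/2), affection (1 = unaffected, 2 = affected, 0 = unknown).
#' \code{"0"} marks a missing parent.
#'
#' @param path file path.
#' @return \code{readPed}: a \code{\link{Pedigree}}.
#' @export
readPed <- function(path) {
  p <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(p) != 6) stop("PED file must have exactly 6 columns")
  names(p) <- c("fam", "id", "father", "mother", "sex", "affected")
  p$sex <- as.integer(p$sex)
  p$affected <- as.integer(p$affected)
  new("Pedigree", ped = p)
}

#' @rdname readPed
#' @param ped a \code{\link{Pedigree}} to write.
#' @export
writePed <- function(ped, path) {
  utils::write.table(pedTable(ped), path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
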