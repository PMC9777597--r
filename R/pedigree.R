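## Pedigree construction, topological sorting, and the numerator
## relationship matrix by the tabular method.

#' Construct a Pedigree from id/sire/dam records
#'
#' Records may be given in any order; parents referenced but never listed
#' are auto-inserted as founders (with a warning) and the pedigree is
#' topologically sorted so every parent precedes its offspring.  Unknown
#' parents may be coded as \code{NA}, \code{""} or \code{"0"}.
#'
#' @param id character (or coercible) vector of individual ids.
#' @param sire,dam parent ids, same length as \code{id}; NA/""/"0" = unknown.
#' @return a \linkS4class{Pedigree}.
#' @examples
#' ped <- Pedigree(c("C", "A", "B"), c("A", NA, NA), c("B", NA, NA))
#' pedId(ped)
#' @export
Pedigree <- function(id, sire = NA, dam = NA) {
  id <- as.character(id)
  norm <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p %in% c("", "0", "NA")] <- NA_character_
    p
  }
  sire <- rep_len(norm(sire), length(id))
  dam <- rep_len(norm(dam), length(id))
  if (anyDuplicated(id))
    stop("duplicate individual ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))

  parents <- unique(c(sire, dam))
  missing <- setdiff(parents[!is.na(parents)], id)
  if (length(missing)) {
    warning("parent id(s) not listed as individuals, added as founders: ",
            paste(missing, collapse = ", "))
    id <- c(id, missing)
    sire <- c(sire, rep(NA_character_, length(missing)))
    dam <- c(dam, rep(NA_character_, length(missing)))
  }

  ## Kahn topological sort; a leftover node means a cycle through it
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- integer(n)
  init <- which(indeg == 0L)
  queue[seq_along(init)] <- init
  tail <- length(init)
  head <- 0L
  order <- integer(0)
  while (head < tail) {
    head <- head + 1L
    v <- queue[head]
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) {
        tail <- tail + 1L
        queue[tail] <- k
      }
    }
  }
  order <- queue[seq_len(tail)]
  if (length(order) < n) {
    offending <- id[setdiff(seq_len(n), order)][1L]
    stop("pedigree contains a cycle involving individual '", offending, "'")
  }
  id2 <- id[order]
  pos <- match(seq_len(n), order)  # old index -> new rank
  conv <- function(p) {
    out <- integer(n)
    known <- !is.na(p)
    out[known] <- pos[p[known]]
    out[order]
  }
  new("Pedigree", id = id2, sire = conv(si), dam = conv(di))
}

#' Sort raw pedigree records into a Pedigree
#'
#' Thin wrapper around [Pedigree()] for data.frame input with columns
#' id, sire, dam (any order of rows).
#'
#' @param records data.frame with columns \code{id}, \code{sire}, \code{dam}.
#' @return a topologically sorted \linkS4class{Pedigree}.
#' @export
sortPedigree <- function(records) {
  stopifnot(all(c("id", "sire", "dam") %in% names(records)))
  Pedigree(records$id, records$sire, records$dam)
}

#' @rdname Pedigree-class
#' @param object,x a \linkS4class{Pedigree}.
#' @export
pedId <- function(x) x@id

#' @rdname Pedigree-class
#' @export
nIndividuals <- function(x) length(x@id)

#' @rdname Pedigree-class
#' @export
setMethod("founders", "Pedigree", function(x) x@id[x@sire == 0L & x@dam == 0L])

#' Pedigree as a data.frame
#'
#' @param x a \linkS4class{Pedigree}.
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return data.frame with character columns id, sire, dam (NA = unknown).
#' @export
as.data.frame.Pedigree <- function(x, row.names = NULL, optional = FALSE, ...) {
  look <- function(p) ifelse(p == 0L, NA_character_, x@id[pmax(p, 1L)])
  data.frame(id = x@id, sire = look(x@sire), dam = look(x@dam),
             stringsAsFactors = FALSE)
}

setMethod("show", "Pedigree", function(object) {
  nf <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", length(object@id), "individuals (", nf, "founders )\n")
})

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive genetic relationship matrix A from a sorted
#' pedigree: processing individuals in order, a_ij = (a_{j,sire(i)} +
#' a_{j,dam(i)})/2 for previously processed j, and a_ii = 1 +
#' a_{sire(i),dam(i)}/2, with unknown parents contributing zero.  The
#' diagonal therefore carries inbreeding exactly (a_ii = 1 + F_i).
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @return dense symmetric matrix with dimnames set to the pedigree ids;
#'   entries are twice the kinship coefficients.
#' @examples
#' ped <- Pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
#' buildA(ped)["S", "X"]  # parent-offspring: 0.5
#' @export
buildA <- function(pedigree) {
  stopifnot(is(pedigree, "Pedigree"))
  n <- length(pedigree@id)
  A <- matrix(0, n, n, dimnames = list(pedigree@id, pedigree@id))
  s <- pedigree@sire
  d <- pedigree@dam
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    if (s[i] > 0L) row <- row + A[prev, s[i]]
    if (d[i] > 0L) row <- row + A[prev, d[i]]
    row <- row / 2
    A[i, prev] <- row
    A[prev, i] <- row
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] / 2 else 0
  }
  A
}

#' Truncate a pedigree to k ancestral generations
#'
#' Keeps the focal individuals plus ancestors up to \code{k} parent steps
#' (k = 3: parents, grandparents, great-grandparents); links to dropped
#' ancestors become unknown.  Mirrors the common practice of tracing the
#' pedigree back a fixed number of generations before building A.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param ids focal individual ids (default: individuals that are nobody's
#'   parent, i.e. the phenotyped generation).
#' @param k number of ancestral generations to retain (default 3).
#' @return a \linkS4class{Pedigree} restricted to the retained individuals.
#' @export
truncateGenerations <- function(pedigree, ids = NULL, k = 3) {
  stopifnot(is(pedigree, "Pedigree"))
  n <- length(pedigree@id)
  if (is.null(ids)) {
    isParent <- logical(n)
    isParent[pedigree@sire[pedigree@sire > 0L]] <- TRUE
    isParent[pedigree@dam[pedigree@dam > 0L]] <- TRUE
    ids <- pedigree@id[!isParent]
  }
  keep <- match(ids, pedigree@id)
  if (anyNA(keep)) stop("unknown focal id(s): ",
                        paste(ids[is.na(keep)], collapse = ", "))
  current <- keep
  all <- keep
  for (g in seq_len(k)) {
    par <- c(pedigree@sire[current], pedigree@dam[current])
    par <- unique(par[par > 0L])
    current <- setdiff(par, all)
    all <- c(all, current)
    if (!length(current)) break
  }
  sel <- sort(all)
  inSel <- logical(n)
  inSel[sel] <- TRUE
  look <- function(p, i) if (p[i] > 0L && inSel[p[i]]) pedigree@id[p[i]] else NA_character_
  Pedigree(pedigree@id[sel],
           vapply(sel, function(i) look(pedigree@sire, i), character(1)),
           vapply(sel, function(i) look(pedigree@dam, i), character(1)))
}

#' Read / write a pedigree CSV (id, sire, dam; 0 or empty = unknown)
#'
#' @param path file path.
#' @return \code{readPedigree}: a \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
  df <- read.csv(path, colClasses = "character")
  sortPedigree(df)
}

#' @rdname readPedigree
#' @param pedigree a \linkS4class{Pedigree}.
#' @export
writePedigree <- function(pedigree, path) {
  df <- as.data.frame(pedigree)
  df[is.na(df)] <- "0"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
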