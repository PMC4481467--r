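#' Construct a pedigree
#'
#' @param id individual identifiers (unique).
#' @param father,mother parent identifiers; `NA` or `"0"` for founders.
#'   Half-known parentage (exactly one parent recorded) is completed with a
#'   dummy founder so that every individual has both parents or none.
#' @param family optional family labels.
#' @param sex optional sex codes (1 = male, 2 = female, 0 = unknown),
#'   retained only for file round-trips.
#' @return Object of class `pedigree_df`: a data.frame with columns
#'   `family`, `id`, `father`, `mother`, `sex`.
#' @export
pedigree <- function(id, father, mother, family = NULL, sex = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  norm <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "0" | p == ""] <- NA_character_
    p
  }
  father <- norm(father); mother <- norm(mother)
  if (is.null(family)) family <- rep("F1", length(id))
  if (is.null(sex)) sex <- rep(0L, length(id))
  ped <- data.frame(family = as.character(family), id = id,
                    father = father, mother = mother,
                    sex = as.integer(sex), stringsAsFactors = FALSE)

  # complete half-known parents with dummy founders
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half)) {
    for (i in which(half)) {
      dummy <- paste0(".dummy", i)
      ped <- rbind(ped, data.frame(family = ped$family[i], id = dummy,
                                   father = NA_character_,
                                   mother = NA_character_,
                                   sex = 0L, stringsAsFactors = FALSE))
      if (is.na(ped$father[i])) ped$father[i] <- dummy else ped$mother[i] <- dummy
    }
  }
  for (col in c("father", "mother")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(bad))
      stop("unknown parent identifier(s): ",
           paste(unique(ped[[col]][bad]), collapse = ", "))
  }
  ped <- .ped_toposort(ped)
  class(ped) <- c("pedigree_df", "data.frame")
  ped
}

# topological sort, parents before offspring; errors on cycles
.ped_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order) < n) stop("cycle detected in pedigree")
  ped[order, , drop = FALSE]
}

#' Expected relationship matrix from a pedigree
#'
#' Computes R = 2 * kinship by the standard recursion
#' phi(i, i) = (1 + phi(f_i, m_i)) / 2 and
#' phi(i, j) = (phi(f_i, j) + phi(m_i, j)) / 2 for j preceding i, so that
#' unrelated founders give R = I and the polygenic variance in the mixed
#' model is the usual additive variance.
#'
#' @param ped a [pedigree()].
#' @param ids optional subset/ordering of individuals for the returned
#'   matrix (the full pedigree is always used for the recursion).
#' @return symmetric relationship matrix with dimnames = ids.
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree_df"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  fa <- unname(idx[ped$father]); mo <- unname(idx[ped$mother])
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- fa[i]; m <- mo[i]
    if (is.na(f)) {              # founder
      phi[i, i] <- 0.5
    } else {
      if (i > 1L) {
        j <- seq_len(i - 1L)
        phi[i, j] <- (phi[f, j] + phi[m, j]) / 2
        phi[j, i] <- phi[i, j]
      }
      phi[i, i] <- (1 + phi[f, m]) / 2
    }
  }
  R <- 2 * phi
  dimnames(R) <- list(ped$id, ped$id)
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (!all(ids %in% ped$id))
      stop("ids not present in pedigree: ",
           paste(setdiff(ids, ped$id), collapse = ", "))
    R <- R[ids, ids, drop = FALSE]
  }
  R
}

#' Read a PED/FAM-style pedigree file
#'
#' Whitespace-delimited columns: family_id, individual_id, father_id,
#' mother_id, sex; `"0"` codes a missing parent.
#'
#' @param path file path.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 5L) stop("FAM file needs >= 5 columns")
  pedigree(id = tab[[2]], father = tab[[3]], mother = tab[[4]],
           family = tab[[1]], sex = tab[[5]])
}

#' Read a precomputed square relationship matrix
#'
#' Tab-delimited, first row and first column hold individual ids.
#'
#' @param path file path.
#' @param tol maximum tolerated asymmetry.
#' @return symmetric numeric matrix with dimnames.
#' @export
read_kinship <- function(path, tol = 1e-8) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1L, sep = "\t",
                           check.names = FALSE)
  R <- as.matrix(tab)
  if (nrow(R) != ncol(R)) stop("relationship matrix is not square")
  if (anyDuplicated(rownames(R))) stop("duplicate ids in relationship matrix")
  if (!identical(rownames(R), colnames(R)))
    stop("row and column ids of the relationship matrix differ")
  if (max(abs(R - t(R))) > tol)
    stop("relationship matrix asymmetric beyond tolerance")
  R <- (R + t(R)) / 2
  R
}
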