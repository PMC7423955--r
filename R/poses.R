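#' Ligand pose: labelled coordinate set with optional ordering score
#'
#' All poses compared or clustered together must share the same atom
#' count and atom ordering.
#'
#' @param label pose identifier
#' @param coordinates numeric matrix, one atom per row, columns x/y/z
#'   (Angstrom)
#' @param score optional ordering value (e.g. docking score); better
#'   poses have higher scores for clustering purposes
#' @return object of class `pose`
#' @export
pose <- function(label, coordinates, score = NA_real_) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3 || nrow(coordinates) < 1) {
    stop("coordinates must be an n x 3 matrix")
  }
  if (any(!is.finite(coordinates))) stop("non-finite coordinates")
  structure(list(label = as.character(label), coordinates = coordinates,
                 score = as.numeric(score)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose %s: %d atoms%s\n", x$label, nrow(x$coordinates),
              if (is.na(x$score)) "" else sprintf(", score %g", x$score)))
  invisible(x)
}

#' Root mean square deviation between two poses
#'
#' Plain coordinate RMSD by default: docked poses share the receptor
#' frame, so no alignment is wanted. With `superpose = TRUE` the poses
#' are optimally superposed (centroid shift plus least-squares
#' rotation) before the deviation is computed, which can only lower the
#' result.
#'
#' @param a,b [pose()] objects with matching atom counts and ordering
#' @param superpose superpose before computing? default FALSE
#' @return RMSD in Angstrom; symmetric in `a` and `b`
#' @examples
#' p1 <- pose("a", diag(3))
#' p2 <- pose("b", diag(3) + 1) # rigid shift by (1,1,1)
#' rmsd(p1, p2) # sqrt(3)
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  stopifnot(inherits(a, "pose"), inherits(b, "pose"))
  if (nrow(a$coordinates) != nrow(b$coordinates)) {
    stop(sprintf("atom count mismatch: %d vs %d", nrow(a$coordinates),
                 nrow(b$coordinates)))
  }
  if (superpose) {
    xa <- as.numeric(t(a$coordinates))
    xb <- as.numeric(t(b$coordinates))
    return(as.numeric(bio3d::rmsd(xa, xb, fit = TRUE)))
  }
  sqrt(mean(rowSums((a$coordinates - b$coordinates)^2)))
}

#' Reverse clustering of docked poses
#'
#' Greedy leader clustering that winnows a pose set to mutually
#' distinct representatives: poses are visited best score first (ties
#' and missing scores fall back to stable input order); a pose becomes
#' a new representative iff its RMSD to every existing representative
#' strictly exceeds the cutoff, otherwise it is assigned to its nearest
#' representative. Retained representatives are therefore pairwise more
#' than `cutoff` apart, giving diverse coverage of candidate binding
#' modes.
#'
#' @param poses list of [pose()] objects (non-empty, consistent atom
#'   counts)
#' @param cutoff RMSD distinctness threshold, Angstrom (> 0); the
#'   conventional pose-filter value is 3.0
#' @param superpose superpose poses before RMSD? default FALSE (shared
#'   docking frame)
#' @return object of class `cluster_result`: list with
#'   `representatives` (labels in visit order) and `assignment` (named
#'   character vector pose label -> representative label; every
#'   representative maps to itself)
#' @export
reverse_cluster <- function(poses, cutoff = 3.0, superpose = FALSE) {
  if (length(poses) == 0) stop("empty pose set")
  stopifnot(all(vapply(poses, inherits, logical(1), "pose")))
  if (cutoff <= 0) stop("cutoff must be > 0")
  labels <- vapply(poses, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("pose labels must be unique")
  scores <- vapply(poses, `[[`, numeric(1), "score")
  ord <- order(-ifelse(is.na(scores), -Inf, scores), seq_along(poses))
  reps <- integer(0)
  assignment <- character(length(poses))
  names(assignment) <- labels
  for (i in ord) {
    if (length(reps) == 0) {
      reps <- i
      assignment[labels[i]] <- labels[i]
      next
    }
    d <- vapply(reps, function(j) rmsd(poses[[i]], poses[[j]],
                                       superpose = superpose), numeric(1))
    if (all(d > cutoff)) {
      reps <- c(reps, i)
      assignment[labels[i]] <- labels[i]
    } else {
      assignment[labels[i]] <- labels[reps[which.min(d)]]
    }
  }
  structure(list(representatives = labels[reps], assignment = assignment),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("reverse clustering: %d poses -> %d representatives\n",
              length(x$assignment), length(x$representatives)))
  invisible(x)
}

#' Read poses from a concatenated XYZ file
#'
#' Parses the plain XYZ dialect: repeated blocks of an atom-count line,
#' a comment line (used as the pose label; a `score=<x>` token in it is
#' parsed as the pose score), and one `element x y z` line per atom.
#'
#' @param path path to the XYZ file
#' @return list of [pose()] objects
#' @export
read_poses_xyz <- function(path) {
  lines <- readLines(path)
  poses <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]))
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("truncated XYZ block starting at line %d", i))
    }
    comment <- trimws(lines[i + 1L])
    k <- k + 1L
    label <- if (nzchar(comment)) sub("\\s*score=.*$", "", comment) else
      paste0("pose", k)
    if (!nzchar(label)) label <- paste0("pose", k)
    score <- NA_real_
    sm <- regmatches(comment, regexpr("score=\\S+", comment))
    if (length(sm) == 1 && nzchar(sm)) {
      score <- suppressWarnings(as.numeric(sub("score=", "", sm)))
    }
    rows <- lines[(i + 2L):(i + 1L + n)]
    parsed <- lapply(seq_along(rows), function(j) {
      tok <- strsplit(trimws(rows[j]), "\\s+")[[1]]
      if (length(tok) < 4) {
        stop(sprintf("line %d: malformed XYZ atom line", i + 1L + j))
      }
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz))) {
        stop(sprintf("line %d: non-numeric coordinate", i + 1L + j))
      }
      xyz
    })
    poses[[k]] <- pose(label, do.call(rbind, parsed), score)
    i <- i + 2L + n
  }
  if (length(poses) == 0) stop("no poses found in ", path)
  poses
}

#' Read poses from a multi-model PDB file
#'
#' Each MODEL block becomes one pose; labels are `model<N>`.
#'
#' @param path path to a multi-model PDB file
#' @return list of [pose()] objects
#' @export
read_poses_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(i) {
    pose(paste0("model", i), matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  })
}

#' Write a clustering result as a pose-list CSV
#'
#' @param result a [reverse_cluster()] result
#' @param path output CSV path
#' @return the written data frame, invisibly
#' @export
write_cluster_csv <- function(result, path) {
  stopifnot(inherits(result, "cluster_result"))
  df <- data.frame(pose = names(result$assignment),
                   representative = unname(result$assignment),
                   is_representative = names(result$assignment) %in%
                     result$representatives)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
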