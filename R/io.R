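# Serialization and interchange formats.
#
# Datasets, trajectories, maps and models serialize losslessly to RDS (R's
# native named-array container). Extended-XYZ export carries per-atom force
# columns; 1-D/2-D systems pad unused dimensions with zeros and record the
# true dimensionality in the comment line. PDB export writes CG bead records
# (export only).

#' Write / read a dataset container
#'
#' Lossless round trip of a [fine_dataset()] (positions, forces, weights,
#' metadata) through a single-file array container.
#'
#' @param dataset A `fine_dataset`.
#' @param path File path.
#' @return `write_dataset`: the path, invisibly. `read_dataset`: the
#'   restored `fine_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fine_dataset"))
  saveRDS(dataset, path, version = 2)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "fine_dataset")) stop("file does not contain a dataset")
  stopifnot(identical(dim(x$positions), dim(x$forces)))
  x
}

#' Write / read a trajectory container
#'
#' @param traj A [cg_trajectory()].
#' @param path File path.
#' @return `write_traj`: the path, invisibly. `read_traj`: the trajectory.
#' @export
write_traj <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  saveRDS(traj, path, version = 2)
  invisible(path)
}

#' @rdname write_traj
#' @export
read_traj <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "cg_trajectory")) stop("file does not contain a trajectory")
  x
}

.pad3 <- function(mat) {
  out <- matrix(0, nrow(mat), 3)
  out[, seq_len(ncol(mat))] <- mat
  out
}

#' Export frames to extended XYZ
#'
#' One block per frame: an atom count line, a comment line with the frame
#' index, true dimensionality and a `Properties=` descriptor, then one line
#' per site with species, padded 3-D position and (optionally) padded 3-D
#' force columns.
#'
#' @param x A [fine_dataset()], [cg_trajectory()] or frames array.
#' @param path Output file.
#' @param forces Optional forces array overriding the dataset's.
#' @param species Site labels (recycled).
#' @return The path, invisibly.
#' @export
export_xyz <- function(x, path, forces = NULL, species = "X") {
  if (inherits(x, "fine_dataset")) {
    arr <- x$positions
    if (is.null(forces)) forces <- x$forces
  } else if (inherits(x, "cg_trajectory")) {
    arr <- x$frames
  } else arr <- x
  m <- dim(arr)[1]; n <- dim(arr)[2]; d <- dim(arr)[3]
  species <- rep_len(species, n)
  con <- file(path, "w")
  on.exit(close(con))
  props <- if (is.null(forces)) "Properties=species:S:1:pos:R:3"
           else "Properties=species:S:1:pos:R:3:forces:R:3"
  for (i in seq_len(m)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame=%d dim=%d %s", i, d, props), con)
    P <- .pad3(.frame(arr, i))
    if (!is.null(forces)) {
      Fr <- .pad3(.frame(forces, i))
      writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                         species, P[, 1], P[, 2], P[, 3],
                         Fr[, 1], Fr[, 2], Fr[, 3]), con)
    } else {
      writeLines(sprintf("%s %.10g %.10g %.10g",
                         species, P[, 1], P[, 2], P[, 3]), con)
    }
  }
  invisible(path)
}

#' Import an extended-XYZ trajectory with forces as a dataset
#'
#' Reads blocks written by [export_xyz()] (or compatible writers with force
#' columns). Positions and forces in physical units are converted to thermal
#' units by dividing forces by `kT` (e.g. forces in kcal/(mol A) with
#' `kT = 0.5922` kcal/mol at 298 K).
#'
#' @param path Input file.
#' @param dim True dimensionality; defaults to the `dim=` comment field or 3.
#' @param kT Thermal energy used to convert force units (default 1: already
#'   thermal).
#' @return A [fine_dataset()].
#' @export
read_xyz_dataset <- function(path, dim = NULL, kT = 1) {
  lines <- readLines(path)
  pos_list <- list(); frc_list <- list()
  i <- 1; k <- 0
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("corrupt XYZ: expected an atom count line")
    comment <- lines[i + 1]
    if (i + 1 + n > length(lines)) stop("truncated XYZ block")
    if (is.null(dim)) {
      mt <- regmatches(comment, regexec("dim=([0-9]+)", comment))[[1]]
      dim <- if (length(mt) == 2) as.integer(mt[2]) else 3L
    }
    block <- lines[i + 1 + seq_len(n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    nums <- t(vapply(toks, function(tk) as.numeric(tk[-1]),
                     numeric(length(toks[[1]]) - 1)))
    if (ncol(nums) < 6) stop("XYZ lacks force columns")
    k <- k + 1
    pos_list[[k]] <- array(nums[, seq_len(dim), drop = FALSE],
                           dim = c(1, n, dim))
    frc_list[[k]] <- array(nums[, 3 + seq_len(dim), drop = FALSE] / kT,
                           dim = c(1, n, dim))
    i <- i + 2 + n
  }
  fine_dataset(abind_frames(pos_list), abind_frames(frc_list),
               metadata = list(source = path, kT = kT))
}

#' Export a CG structure (or trajectory snapshots) to PDB
#'
#' CG beads as HETATM-free ATOM records with site names; models per frame.
#' Unused spatial dimensions are padded with zeros.
#'
#' @param x A configuration matrix, frames array or [cg_trajectory()].
#' @param path Output file.
#' @param site_names Bead names (recycled).
#' @return The path, invisibly.
#' @export
export_pdb <- function(x, path, site_names = "CG") {
  arr <- if (inherits(x, "cg_trajectory")) x$frames
         else if (length(dim(x)) == 3L) x
         else array(as.matrix(x), dim = c(1, nrow(as.matrix(x)),
                                          ncol(as.matrix(x))))
  m <- dim(arr)[1]; n <- dim(arr)[2]
  site_names <- rep_len(site_names, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(m)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    P <- .pad3(.frame(arr, i))
    for (a in seq_len(n)) {
      writeLines(sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                         a, substr(site_names[a], 1, 4), "CGB", a,
                         P[a, 1], P[a, 2], P[a, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
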