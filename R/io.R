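# Trajectory I/O (extended XYZ and a LAMMPS-dump-compatible dialect,
# orthogonal boxes only), YAML run configuration, and provenance hashing.

#' Write a trajectory
#'
#' `dialect = "xyz"` writes extended XYZ: per frame an atom count, a comment
#' line with `Lattice="Lx 0 0 0 Ly 0 0 0 Lz" Properties=species:S:1:pos:R:3
#' Time=<step>`, then one `label x y z` row per bead.  `dialect = "dump"`
#' writes the LAMMPS dump text format (ITEM: TIMESTEP / NUMBER OF ATOMS /
#' BOX BOUNDS pp pp pp / ATOMS id type x y z).  Positions are written with
#' 1e-6 nm precision; round trips are lossless to that precision.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @param dialect `"xyz"` or `"dump"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("xyz", "dump")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(traj, "cg_trajectory"))
  labels <- .type_labels[traj$type]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    p <- traj$frames[[i]]
    step <- if (length(traj$steps) >= i) traj$steps[i] else i
    if (dialect == "xyz") {
      writeLines(as.character(nrow(p)), con)
      writeLines(sprintf(
        paste0('Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" ',
               'Properties=species:S:1:pos:R:3 Time=%d'),
        traj$box[1], traj$box[2], traj$box[3], step), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", labels, p[, 1], p[, 2],
                         p[, 3]), con)
    } else {
      writeLines(c("ITEM: TIMESTEP", as.character(step),
                   "ITEM: NUMBER OF ATOMS", as.character(nrow(p)),
                   "ITEM: BOX BOUNDS pp pp pp",
                   sprintf("%.6f %.6f", 0, traj$box[1]),
                   sprintf("%.6f %.6f", 0, traj$box[2]),
                   sprintf("%.6f %.6f", 0, traj$box[3]),
                   "ITEM: ATOMS id type x y z"), con)
      writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(nrow(p)),
                         traj$type, p[, 1], p[, 2], p[, 3]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory
#'
#' Parses the formats written by [write_trajectory()].  Triclinic dump boxes
#' (`BOX BOUNDS xy xz yz`) are rejected as unsupported.  Bead metadata not
#' stored in the file (radii, molecule ids) can be supplied via `template`,
#' a `cg_trajectory` whose per-bead fields are reused.
#'
#' @param path Input file.
#' @param dialect `"xyz"` or `"dump"`.
#' @param template Optional `cg_trajectory` supplying bead metadata.
#' @return A `cg_trajectory`.
#' @export
read_trajectory <- function(path, dialect = c("xyz", "dump"),
                            template = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  frames <- list(); steps <- integer(0)
  types <- NULL; box <- NULL
  i <- 1L
  if (dialect == "xyz") {
    while (i <= length(lines)) {
      n <- suppressWarnings(as.integer(lines[i]))
      if (is.na(n)) stop("malformed XYZ header at line ", i)
      cm <- lines[i + 1]
      lat <- regmatches(cm, regexec('Lattice="([^"]+)"', cm))[[1]][2]
      if (is.na(lat)) stop("missing Lattice in XYZ comment line")
      lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
      if (any(lv[c(2, 3, 4, 6, 7, 8)] != 0)) {
        stop("unsupported format: non-orthogonal lattice")
      }
      box <- lv[c(1, 5, 9)]
      tm <- regmatches(cm, regexec("Time=([0-9]+)", cm))[[1]][2]
      steps <- c(steps, if (is.na(tm)) length(frames) + 1L
                 else as.integer(tm))
      rows <- lines[(i + 2):(i + 1 + n)]
      if (length(rows) != n || anyNA(rows)) {
        stop("inconsistent atom count in XYZ frame")
      }
      parts <- strsplit(trimws(rows), "\\s+")
      lab <- vapply(parts, `[[`, character(1), 1)
      xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      ty <- match(lab, .type_labels)
      if (anyNA(ty)) stop("unknown bead label in XYZ file")
      if (is.null(types)) types <- ty
      frames[[length(frames) + 1L]] <- xyz
      i <- i + 2L + n
    }
  } else {
    while (i <= length(lines)) {
      if (!startsWith(lines[i], "ITEM: TIMESTEP")) {
        stop("malformed dump header at line ", i)
      }
      step <- as.integer(lines[i + 1])
      n <- as.integer(lines[i + 3])
      bb <- lines[i + 4]
      if (grepl("xy xz yz", bb)) {
        stop("unsupported format: triclinic box bounds")
      }
      bl <- lapply(lines[(i + 5):(i + 7)], function(l) {
        as.numeric(strsplit(trimws(l), "\\s+")[[1]])
      })
      box <- vapply(bl, function(b) b[2] - b[1], numeric(1))
      rows <- lines[(i + 9):(i + 8 + n)]
      if (length(rows) != n || anyNA(rows)) {
        stop("inconsistent atom count in dump frame")
      }
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                 as.numeric))
      o <- order(m[, 1])
      m <- m[o, , drop = FALSE]
      if (is.null(types)) types <- as.integer(m[, 2])
      frames[[length(frames) + 1L]] <- m[, 3:5, drop = FALSE]
      steps <- c(steps, step)
      i <- i + 9L + n
    }
  }
  n <- length(types)
  base <- if (!is.null(template)) {
    template
  } else {
    list(mol = integer(n), is_polymer = rep(FALSE, n),
         radius_by_type = c(0.3, 0.3, 1.0, 1.5),
         virtual_by_type = c(TRUE, TRUE, FALSE, FALSE),
         dt = NA_real_, record_every = NA_integer_, temperature = 300,
         client_R = 0, client_ra = 0)
  }
  structure(list(
    frames = frames, images = NULL, steps = steps, type = types,
    mol = base$mol, is_polymer = base$is_polymer, box = box,
    radius_by_type = base$radius_by_type,
    virtual_by_type = base$virtual_by_type,
    dt = base$dt, record_every = base$record_every,
    temperature = base$temperature,
    client_R = base$client_R, client_ra = base$client_ra
  ), class = "cg_trajectory")
}

#' Read a YAML run configuration
#'
#' Maps a YAML file with optional sections `topology` (arguments of
#' [cg_topology()]), `forcefield` ([cg_forcefield()] overrides),
#' `config` ([sim_config()]), `insertion_model` ([insertion_model()]) and
#' `composition` ([phi_from_composition()] arguments) onto constructed
#' objects.  The returned list carries the provenance hash of the raw file
#' contents as attribute `"config_hash"`.
#'
#' @param path YAML file.
#' @return Named list of constructed objects (missing sections are NULL).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(
    topology = if (!is.null(raw$topology)) {
      do.call(cg_topology, raw$topology)
    },
    config = if (!is.null(raw$config)) do.call(sim_config, raw$config),
    insertion_model = if (!is.null(raw$insertion_model)) {
      do.call(insertion_model, raw$insertion_model)
    },
    composition = raw$composition,
    forcefield = raw$forcefield
  )
  if (!is.null(out$topology)) {
    ffargs <- c(list(topology = out$topology),
                if (is.list(raw$forcefield)) raw$forcefield)
    out$forcefield <- do.call(default_forcefield, ffargs)
  }
  attr(out, "config_hash") <- config_hash(raw)
  out
}

#' Provenance hash of a configuration object
#'
#' Polynomial rolling hash (two independent prime-modulus lanes) of the
#' deparsed object, rendered as 16 hex digits; stable across sessions for
#' plain lists of scalars.
#'
#' @param x Any R object.
#' @return A 16-character hex string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h1 <- 2166136261 %% 2147483647
  h2 <- 40389 # arbitrary non-zero start for the second lane
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 37 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
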