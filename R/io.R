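#' Read DNA sequences from FASTA or plain text
#'
#' FASTA is parsed with Biostrings; plain format is one sequence per line
#' (trailing blank lines ignored). Sequences are uppercased; characters
#' other than A, C, G, T, N are an error naming the offending line.
#'
#' @param path File path.
#' @param format `"auto"` (default: FASTA iff the first non-blank line
#'   starts with `>`), `"fasta"` or `"plain"`.
#' @param quiet Suppress the per-file report (count, length range).
#' @return Character vector of reads.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "plain"),
                           quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0) stop("empty sequence file: ", path)
  if (format == "auto") {
    format <- if (startsWith(trimws(nonblank[1]), ">")) "fasta" else "plain"
  }
  if (format == "fasta") {
    reads <- toupper(as.character(Biostrings::readDNAStringSet(path)))
    names(reads) <- NULL
  } else {
    reads <- toupper(trimws(nonblank))
    bad <- which(!grepl("^[ACGTN]+$", reads))
    if (length(bad) > 0) {
      lineno <- match(nonblank[bad[1]], lines)
      stop("non-nucleotide characters at line ", lineno, " of ", path)
    }
  }
  bad <- which(!grepl("^[ACGTN]+$", reads))
  if (length(bad) > 0) stop("non-nucleotide characters in record ", bad[1])
  if (!quiet) {
    message(length(reads), " reads from ", basename(path), "; lengths ",
            min(nchar(reads)), "-", max(nchar(reads)))
  }
  reads
}

#' Write / read an ADM in the 16 x l text format
#'
#' The format is a header line `>name length=l` followed by 16
#' tab-separated rows labelled AA..TT (first letter = predecessor), each
#' with l probability columns; column 1 is the initial distribution
#' replicated across predecessor rows. Probabilities are printed with 8
#' significant digits, so a write/read round trip is stable at that
#' precision.
#'
#' @param x An `adm`.
#' @param path Output file.
#' @export
write_adm <- function(x, path) {
  m <- as_dinuc_matrix(x)
  name <- if (is.null(x$name)) "adm" else x$name
  lines <- c(
    paste0(">", name, " length=", x$length),
    vapply(seq_len(16), function(r) {
      paste(c(DINUC_LABELS[r], formatC(m[r, ], format = "g", digits = 8)),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_adm
#' @param tol Row-sum tolerance when validating the loaded matrix
#'   (default 1e-5).
#' @export
read_adm <- function(path, tol = 1e-5) {
  lines <- readLines(path)
  if (length(lines) < 17 || !startsWith(lines[1], ">")) {
    stop("not an ADM file (expected '>name length=l' header): ", path)
  }
  name <- sub("^>(\\S+).*", "\\1", lines[1])
  fields <- strsplit(lines[2:17], "\t", fixed = TRUE)
  labels <- vapply(fields, `[`, "", 1)
  if (!identical(labels, DINUC_LABELS)) {
    stop("ADM rows must be labelled AA..TT in order: ", path)
  }
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1])))
  rownames(m) <- DINUC_LABELS
  x <- tryCatch(from_dinuc_matrix(round_renorm(m, tol), name = name),
                error = function(e) stop("invalid ADM in ", path, ": ",
                                         conditionMessage(e)))
  x
}

# Validate row sums within tol, then renormalize exactly (absorbs printed
# rounding).
round_renorm <- function(m, tol) {
  l <- ncol(m)
  for (a in 1:4) {
    rows <- (a - 1) * 4 + 1:4
    for (h in seq_len(l)) {
      s <- sum(m[rows, h])
      if (abs(s - 1) > tol) {
        stop("row sums deviate from 1 by ", signif(abs(s - 1), 3),
             " (predecessor ", DNA_BASES[a], ", column ", h, ")")
      }
      m[rows, h] <- m[rows, h] / s
    }
  }
  m
}

#' Write / read an order-zero profile (PPM) in the 4-row text format
#'
#' The order-zero analogue of [write_adm()]: a header `>name length=l`
#' followed by 4 tab-separated rows labelled A, C, G, T holding the
#' per-position base probabilities. Reading returns the degenerate ADM
#' whose conditionals do not depend on the predecessor.
#'
#' @param x An `adm`; its per-position marginals are written.
#' @param path File path.
#' @export
write_ppm <- function(x, path) {
  m <- marginals(x)
  name <- if (is.null(x$name)) "ppm" else x$name
  lines <- c(
    paste0(">", name, " length=", x$length),
    vapply(1:4, function(r) {
      paste(c(DNA_BASES[r], formatC(m[r, ], format = "g", digits = 8)),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ppm
#' @param tol Column-sum tolerance when validating (default 1e-5).
#' @export
read_ppm <- function(path, tol = 1e-5) {
  lines <- readLines(path)
  if (length(lines) < 5 || !startsWith(lines[1], ">")) {
    stop("not a PPM file (expected '>name length=l' header): ", path)
  }
  name <- sub("^>(\\S+).*", "\\1", lines[1])
  fields <- strsplit(lines[2:5], "\t", fixed = TRUE)
  if (!identical(vapply(fields, `[`, "", 1), DNA_BASES)) {
    stop("PPM rows must be labelled A, C, G, T in order: ", path)
  }
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1])))
  cs <- colSums(m)
  if (any(abs(cs - 1) > tol)) {
    stop("PPM columns must sum to 1 (worst deviation ",
         signif(max(abs(cs - 1)), 3), "): ", path)
  }
  m <- sweep(m, 2, cs, "/")
  l <- ncol(m)
  trans <- array(0, c(4, 4, l))
  for (h in seq_len(l)) trans[, , h] <- matrix(m[, h], 4, 4, byrow = TRUE)
  adm(m[, 1], trans, name = name)
}

#' Write reads as plain text or FASTA
#'
#' @param reads Character vector of DNA reads.
#' @param path Output file.
#' @param format `"plain"` (one sequence per line, default) or `"fasta"`
#'   (records named `read_1`, `read_2`, ...).
#' @export
write_sequences <- function(reads, path, format = c("plain", "fasta")) {
  format <- match.arg(format)
  if (format == "plain") {
    writeLines(reads, path)
  } else {
    writeLines(as.vector(rbind(paste0(">read_", seq_along(reads)), reads)),
               path)
  }
  invisible(path)
}

#' Save / load a mixture model as a directory bundle
#'
#' The bundle is a directory of small human-readable text files: one
#' `.adm` per monomer, `background.tsv`, `lambda.tsv`, one COB TSV per
#' monomer pair, one bridging `.adm`-style file and one signed deviation
#' TSV per close dimer, and `metadata.yaml` (version stamp, delta, pruned
#' specs). `load_model(save_model(m))` reproduces the model to the printed
#' precision (`model_distance` ~ 0).
#'
#' @param model A `mixture_model`.
#' @param path Bundle directory (created if needed).
#' @return `save_model`: the path, invisibly. `load_model`: the
#'   `mixture_model`.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(model$monomers)) {
    mk <- model$monomers[[k]]
    mk$name <- paste0("monomer", k)
    write_adm(mk, file.path(path, paste0("monomer_", k, ".adm")))
  }
  bg <- model$background
  utils::write.table(
    data.frame(base = DNA_BASES, init = bg$init, bg$trans),
    file.path(path, "background.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  lam <- tibble::tibble(
    component = c("background",
                  paste0("monomer", seq_along(model$monomers)),
                  if (nrow(model$dimers) > 0)
                    dimer_key(model$dimers$k1, model$dimers$k2,
                              model$dimers$orientation, model$dimers$d)),
    lambda = c(model$lambda0, model$lambda_mono, model$dimers$lambda)
  )
  utils::write.table(lam, file.path(path, "lambda.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tb in cob_tables(model)) {
    utils::write.table(
      cob_matrix_display(tb),
      file.path(path, paste0("cob_", tb$k1[1], "_", tb$k2[1], ".tsv")),
      sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA, na = ""
    )
  }
  if (nrow(model$dimers) > 0) {
    devs <- deviations(model)
    for (r in seq_len(nrow(model$dimers))) {
      sp <- model$dimers[r, ]
      if (sp$d >= model$delta) next
      key <- dimer_key(sp$k1, sp$k2, sp$orientation, sp$d)
      fkey <- gsub(",", "_", key)
      psi <- sp$psi[[1]]
      w <- dim(psi)[3]
      coln <- paste0("c", seq_len(w))
      m <- matrix(0, 16, w, dimnames = list(DINUC_LABELS, coln))
      dv <- matrix(0, 16, w, dimnames = list(DINUC_LABELS, coln))
      for (a in 1:4) for (b in 1:4) {
        m[(a - 1) * 4 + b, ] <- psi[a, b, ]
        dv[(a - 1) * 4 + b, ] <- devs[[key]][a, b, ]
      }
      utils::write.table(formatC(m, format = "g", digits = 8),
                         file.path(path, paste0("bridge_", fkey, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(formatC(dv, format = "g", digits = 6),
                         file.path(path, paste0("deviation_", fkey, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }
  meta <- list(
    format = "admotif-bundle", version = 1L,
    package_version = as.character(utils::packageVersion("admotif")),
    delta = model$delta,
    n_monomers = length(model$monomers),
    dimers = if (nrow(model$dimers) > 0) {
      lapply(seq_len(nrow(model$dimers)), function(r) {
        list(k1 = model$dimers$k1[r], k2 = model$dimers$k2[r],
             orientation = model$dimers$orientation[r],
             d = model$dimers$d[r])
      })
    } else list(),
    pruned = if (nrow(model$pruned) > 0) {
      lapply(seq_len(nrow(model$pruned)), function(r) {
        list(k1 = model$pruned$k1[r], k2 = model$pruned$k2[r],
             orientation = model$pruned$orientation[r],
             d = model$pruned$d[r])
      })
    } else list(),
    background_order = model$background$order
  )
  yaml::write_yaml(meta, file.path(path, "metadata.yaml"))
  invisible(path)
}

cob_matrix_display <- function(tb) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tb, "orientation", "d", "display"),
    names_from = "d", values_from = "display"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$orientation
  m
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  metaf <- file.path(path, "metadata.yaml")
  if (!file.exists(metaf)) stop("missing metadata.yaml in ", path)
  meta <- yaml::read_yaml(metaf)
  bgt <- utils::read.table(file.path(path, "background.tsv"), header = TRUE,
                           sep = "\t")
  bg <- if (identical(meta$background_order, 1L) ||
            identical(meta$background_order, 1)) {
    background_model(bgt$init, as.matrix(bgt[, 3:6]))
  } else background_model(bgt$init)
  p <- meta$n_monomers
  monomers <- lapply(seq_len(p), function(k) {
    f <- file.path(path, paste0("monomer_", k, ".adm"))
    if (!file.exists(f)) stop("missing monomer file: ", f)
    read_adm(f)
  })
  lam <- utils::read.table(file.path(path, "lambda.tsv"), header = TRUE,
                           sep = "\t")
  lam_of <- function(key) {
    v <- lam$lambda[lam$component == key]
    if (length(v) != 1) stop("missing lambda for ", key, " in ", path)
    v
  }
  lambda_mono <- vapply(paste0("monomer", seq_len(p)), lam_of, 0)
  dimers <- NULL
  if (length(meta$dimers) > 0) {
    rows <- lapply(meta$dimers, function(sp) {
      key <- dimer_key(sp$k1, sp$k2, sp$orientation, sp$d)
      psi <- NULL
      if (sp$d < meta$delta) {
        f <- file.path(path, paste0("bridge_", gsub(",", "_", key), ".tsv"))
        if (!file.exists(f)) stop("missing bridging file: ", f)
        m <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                         row.names = 1, check.names = FALSE))
        w <- ncol(m)
        psi <- array(0, c(4, 4, w))
        for (a in 1:4) for (b in 1:4) psi[a, b, ] <- m[(a - 1) * 4 + b, ]
        # absorb printed rounding
        for (j in seq_len(w)) psi[, , j] <- psi[, , j] / rowSums(psi[, , j])
      }
      tibble::tibble(k1 = sp$k1, k2 = sp$k2, orientation = sp$orientation,
                     d = sp$d, lambda = lam_of(key), psi = list(psi))
    })
    dimers <- dplyr::bind_rows(rows)
  }
  pruned <- if (length(meta$pruned) > 0) {
    dplyr::bind_rows(lapply(meta$pruned, tibble::as_tibble))
  } else NULL
  mixture_model(bg, monomers, lambda_mono, dimers, delta = meta$delta,
                pruned = pruned)
}

#' Export logo-drawing data for an ADM or a deviation matrix
#'
#' The data behind a dinucleotide dependency ("river-lake") logo: per
#' position a circle radius for each base, proportional to its marginal
#' probability, and per junction an edge weight for each dinucleotide,
#' proportional to its joint probability. For deviation matrices the
#' signed weights are split into positive and negative channels. The
#' result serializes directly with [jsonlite::toJSON()].
#'
#' @param x An `adm`, or an `adm_deviation`.
#' @return A list: for an ADM, `radii` (4 x l) and `edges` (list of 4 x 4
#'   joints per junction); for a deviation, `positive` and `negative` edge
#'   channels (entries of magnitude < 1e-12 are dropped).
#' @export
export_logo_data <- function(x) {
  if (inherits(x, "adm")) {
    m <- marginals(x)
    edges <- list()
    if (x$length >= 2) {
      for (h in 2:x$length) {
        edges[[h - 1]] <- m[, h - 1] * x$trans[, , h]
        dimnames(edges[[h - 1]]) <- list(DNA_BASES, DNA_BASES)
      }
    }
    return(list(type = "adm", radii = m, edges = edges))
  }
  if (inherits(x, "adm_deviation")) {
    w <- dim(x)[3]
    channel <- function(sign) {
      out <- list()
      for (j in seq_len(w)) {
        m <- unclass(x)[, , j]
        m <- if (sign > 0) pmax(m, 0) else pmax(-m, 0)
        if (max(m) > 1e-12) {
          dimnames(m) <- list(DNA_BASES, DNA_BASES)
          out[[as.character(j)]] <- m
        }
      }
      out
    }
    return(list(type = "deviation", positive = channel(1),
                negative = channel(-1)))
  }
  stop("x must be an adm or an adm_deviation")
}
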