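## io_formats: readers/writers for the external formats and the shared
## domain containers. All interval containers are 0-based half-open
## internally; GFF3 and wiggle are converted at the boundary.

#' Construct a genome sequence
#'
#' A single chromosome-like sequence over the alphabet `{A,C,G,T,N}`,
#' stored uppercase.
#'
#' @param name Sequence identifier.
#' @param residues Character scalar with the sequence.
#' @return An object of class `genome_sequence` with fields `name`,
#'   `residues` and `length`.
#' @export
genome_sequence <- function(name, residues) {
  residues <- toupper(as.character(residues))
  if (grepl("[^ACGTN]", residues))
    stop("sequence '", name, "' contains characters outside {A,C,G,T,N}")
  structure(list(name = as.character(name), residues = residues,
                 length = nchar(residues)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

# integer encoding used by the scanners: A=0 C=1 G=2 T=3 N=4
encode_sequence <- function(gs) {
  codes <- integer(256)
  codes[] <- 5L
  codes[utf8ToInt("A")] <- 1L; codes[utf8ToInt("C")] <- 2L
  codes[utf8ToInt("G")] <- 3L; codes[utf8ToInt("T")] <- 4L
  codes[utf8ToInt("N")] <- 5L
  codes[utf8ToInt(gs$residues)] - 1L
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (possibly multi-record).
#' @return List of [genome_sequence()] objects in file order; empty list
#'   (with a warning) for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  nm <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set),
         function(i) genome_sequence(nm[i], as.character(set[[i]])))
}

#' Write sequences to FASTA
#' @param seqs List of [genome_sequence()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## ----------------------------------------------------------- weight matrix

#' Construct a weight matrix
#'
#' Per-position nucleotide probabilities of a binding site. Rows are
#' positions, columns `A,C,G,T`; every row sums to one.
#'
#' @param mat Numeric matrix, positions x 4.
#' @param name Identifier.
#' @param pseudocount Probability mass that was added at load time
#'   (recorded, not re-applied).
#' @return An object of class `weight_matrix`.
#' @export
weight_matrix <- function(mat, name = "wm", pseudocount = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1 || ncol(mat) != 4)
    stop("weight matrix must be positions x 4 with length >= 1")
  if (any(!is.finite(mat)) || any(mat <= 0))
    stop("weight matrix entries must be finite and > 0 (apply a pseudocount)")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-9))
    stop("weight matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  colnames(mat) <- c("A", "C", "G", "T")
  structure(mat, name = as.character(name), pseudocount = pseudocount,
            class = c("weight_matrix", "matrix"))
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %s: %d positions, %.3f bits\n",
              attr(x, "name"), nrow(x), information_content(x)))
  invisible(x)
}

wm_length <- function(wm) nrow(wm)

#' Read weight matrices (TRANSFAC-like or JASPAR pfm text)
#'
#' Count matrices get `pseudocount` added to every cell and are then
#' renormalized per row; probability matrices get a floor of 1e-6 and are
#' renormalized.
#'
#' @param path Path to the matrix file (one or more records).
#' @param pseudocount Count added to each cell of count matrices (default
#'   0.5).
#' @return List of [weight_matrix()] objects.
#' @export
read_wm <- function(path, pseudocount = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  out <- list()
  cur_name <- NULL
  cur_rows <- list()
  flush <- function() {
    if (is.null(cur_name) && length(cur_rows) == 0) return(invisible())
    if (length(cur_rows) == 0)
      stop("matrix '", cur_name, "' has length 0")
    mat <- do.call(rbind, cur_rows)
    out[[length(out) + 1]] <<- finish_wm(mat, cur_name, pseudocount)
    cur_name <<- NULL
    cur_rows <<- list()
  }
  jaspar_rows <- NULL
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "XX") ||
        startsWith(ln, "CC")) next
    if (startsWith(ln, ">")) {          # JASPAR header
      flush()
      cur_name <- sub("^>\\s*", "", ln)
      cur_name <- strsplit(cur_name, "\\s+")[[1]][1]
      jaspar_rows <- list()
      next
    }
    if (ln == "//") { flush(); next }
    if (grepl("^(ID|NA)\\s", ln)) {     # TRANSFAC identifier
      flush()
      cur_name <- strsplit(ln, "\\s+")[[1]][2]
      jaspar_rows <- NULL
      next
    }
    if (grepl("^P[O0]\\s", ln)) next    # TRANSFAC column header
    if (grepl("^[ACGT]\\s*\\[", ln) ||
        (!is.null(jaspar_rows) && grepl("^[ACGT]\\s", ln))) {
      # JASPAR base line: "A [ 1 2 3 ]" or "A 1 2 3"
      base <- substr(ln, 1, 1)
      nums <- parse_numbers(gsub("[][]", " ", substr(ln, 2, nchar(ln))), k)
      jaspar_rows[[base]] <- nums
      if (length(jaspar_rows) == 4) {
        lens <- lengths(jaspar_rows)
        if (length(unique(lens)) != 1)
          stop("unequal row lengths for matrix near line ", k)
        mat <- cbind(A = jaspar_rows[["A"]], C = jaspar_rows[["C"]],
                     G = jaspar_rows[["G"]], T = jaspar_rows[["T"]])
        out[[length(out) + 1]] <- finish_wm(mat, cur_name, pseudocount)
        cur_name <- NULL
        jaspar_rows <- NULL
      }
      next
    }
    # TRANSFAC-like numbered (or bare) row: "01  10 0 0 0 [A]"
    toks <- strsplit(ln, "\\s+")[[1]]
    toks <- toks[!grepl("^[ACGTRYKMSWN]$", toks)] # trailing consensus letter
    nums <- parse_numbers(paste(toks, collapse = " "), k)
    if (length(nums) == 5) nums <- nums[-1]       # leading position index
    if (length(nums) != 4)
      stop("cannot parse matrix row at line ", k, ": '", lines[k], "'")
    cur_rows[[length(cur_rows) + 1]] <- nums
  }
  flush()
  if (length(out) == 0) stop("no matrices found in ", path)
  out
}

parse_numbers <- function(s, lineno) {
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  v <- suppressWarnings(as.numeric(toks))
  if (anyNA(v))
    stop("non-numeric matrix cell at line ", lineno, ": '", s, "'")
  v
}

finish_wm <- function(mat, name, pseudocount) {
  if (is.null(name)) name <- paste0("wm", sample.int(1e6, 1))
  rs <- rowSums(mat)
  is_prob <- all(mat <= 1 + 1e-9) && all(abs(rs - 1) < 0.05)
  if (is_prob) {
    mat <- mat + 1e-6
  } else {
    if (pseudocount <= 0 && any(rs == 0))
      stop("matrix '", name, "' has an all-zero row and no pseudocount")
    mat <- mat + pseudocount
    if (any(rowSums(mat) == 0))
      stop("matrix '", name, "' has an all-zero row and no pseudocount")
  }
  mat <- mat / rowSums(mat)
  weight_matrix(mat, name = name, pseudocount = pseudocount)
}

#' Write weight matrices in JASPAR pfm style
#' @param wms A `weight_matrix` or list thereof.
#' @param path Output path.
#' @export
write_wm <- function(wms, path) {
  if (inherits(wms, "weight_matrix")) wms <- list(wms)
  con <- file(path, "w")
  on.exit(close(con))
  for (wm in wms) {
    writeLines(paste0(">", attr(wm, "name")), con)
    for (b in 1:4) {
      writeLines(paste0(c("A", "C", "G", "T")[b], " [ ",
                        paste(sprintf("%.17g", wm[, b]), collapse = " "),
                        " ]"), con)
    }
  }
  invisible(path)
}

## ----------------------------------------------------------------- regions

#' Construct a table of genomic regions
#'
#' Regions are 0-based half-open. `label` is `nucleosome` or `linker`;
#' linkers may carry a `subclass` (`short_linker` or `NFR`).
#'
#' @param chrom,start,end Coordinates (0-based half-open).
#' @param label Region label.
#' @param subclass Linker subclass (`none` for nucleosomes).
#' @param score Optional numeric score (e.g. occupancy or support).
#' @return A `data.frame` of class `genomic_regions`.
#' @export
genomic_regions <- function(chrom, start, end, label = "nucleosome",
                            subclass = "none", score = NA_real_) {
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.integer(start), end = as.integer(end),
                   label = rep_len(as.character(label), n),
                   subclass = rep_len(as.character(subclass), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  validate_regions(df)
}

validate_regions <- function(df) {
  if (nrow(df) > 0) {
    bad <- which(df$start < 0 | df$start >= df$end)
    if (length(bad))
      stop("invalid region(s) with start >= end or start < 0 at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (any(df$subclass != "none" & df$label != "linker"))
      stop("subclass may only be set for linker regions")
  }
  class(df) <- c("genomic_regions", "data.frame")
  df
}

region_name <- function(df) {
  ifelse(df$label == "nucleosome", "nucleosome",
         ifelse(df$subclass == "short_linker", "linker_short",
                ifelse(df$subclass == "NFR", "linker_NFR", "linker")))
}

name_to_label <- function(nm) {
  label <- ifelse(startsWith(nm, "linker"), "linker", "nucleosome")
  subclass <- rep("none", length(nm))
  subclass[nm == "linker_short"] <- "short_linker"
  subclass[nm == "linker_NFR"] <- "NFR"
  list(label = label, subclass = subclass)
}

#' Read regions from a BED file
#'
#' BED coordinates (0-based half-open) are preserved exactly. The name
#' column carries the label (`nucleosome`, `linker`, `linker_short`,
#' `linker_NFR`); the score column, when present, is kept as `score`.
#'
#' @param path Path to a BED file with at least three columns.
#' @return A [genomic_regions()] table.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(genomic_regions(character(), integer(), integer()))
  parts <- strsplit(lines, "\t| +")
  ncol_min <- min(lengths(parts))
  if (ncol_min < 3) stop("BED needs >= 3 columns in ", path)
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stop("non-integer BED coordinate at line ",
         lineno[which(is.na(start) | is.na(end))[1]])
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", lineno[bad[1]], " of ", path)
  nm <- if (ncol_min >= 4) vapply(parts, `[[`, "", 4) else
    rep("nucleosome", length(chrom))
  sc <- if (ncol_min >= 5)
    suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5))) else
      rep(NA_real_, length(chrom))
  lab <- name_to_label(nm)
  genomic_regions(chrom, start, end, lab$label, lab$subclass, sc)
}

#' Write regions to a BED file
#' @param regions A [genomic_regions()] table.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  nm <- region_name(regions)
  sc <- ifelse(is.na(regions$score), "0", sprintf("%.17g", regions$score))
  writeLines(paste(regions$chrom, regions$start, regions$end, nm, sc,
                   sep = "\t"), path)
  invisible(path)
}

## ------------------------------------------------------------------- genes

#' Construct a gene annotation table
#'
#' `tss` and `tes` are 0-based positions of the 5' and 3' ends on the
#' annotated strand.
#'
#' @param gene_id,chrom,strand,tss,tes Per-gene fields; strand is `+`/`-`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, tes) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom), strand = as.character(strand),
                   tss = as.integer(tss), tes = as.integer(tes),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 `gene` features (or all features if none are typed `gene`) and
#' BED6/BED12 lines are supported; the TSS is the 5' end on the annotated
#' strand (start for `+`, end-1 for `-`), 0-based.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return A [gene_annotation()] table.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "+"
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "+"
  }
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  tes <- ifelse(strand == "+", end0 - 1L, start0)
  gene_annotation(as.character(ids),
                  as.character(GenomicRanges::seqnames(gr)), strand, tss, tes)
}

#' Write gene annotations as GFF3
#' @param genes A [gene_annotation()] table.
#' @param path Output path.
#' @export
write_genes <- function(genes, path) {
  start0 <- pmin(genes$tss, genes$tes)
  end0 <- pmax(genes$tss, genes$tes) + 1L
  lines <- c("##gff-version 3",
             paste(genes$chrom, "nucfree", "gene", start0 + 1L, end0,
                   ".", genes$strand, ".",
                   paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## ------------------------------------------------------------------ tracks

#' Construct a per-base coverage track
#'
#' @param chrom Chromosome identifier.
#' @param values Numeric vector, one value per base.
#' @param basis One of `signal`, `probability`, `reads`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, values, basis = "signal") {
  basis <- match.arg(basis, c("signal", "probability", "reads"))
  values <- as.numeric(values)
  if (basis == "probability" &&
      any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("probability-basis track has values outside [0,1]")
  structure(list(chrom = as.character(chrom), values = values, basis = basis),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp (%s), mean %.4g\n", x$chrom,
              length(x$values), x$basis, mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Read a per-base track (bedGraph or fixedStep wiggle)
#'
#' bedGraph intervals are 0-based half-open; fixedStep positions 1-based per
#' the wiggle standard. Sparse gaps are filled with `fill`.
#'
#' @param path Input path; format chosen by extension (`.bedgraph`/`.bg`
#'   versus `.wig`) with a content sniff as fallback.
#' @param length Chromosome length; defaults to the last covered base.
#' @param fill Value for uncovered positions.
#' @param basis Passed to [coverage_track()].
#' @return A [coverage_track()].
#' @export
read_track <- function(path, length = NULL, fill = 0, basis = "signal") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 5)
  is_wig <- grepl("\\.wig$", path, ignore.case = TRUE) ||
    any(grepl("^(fixedStep|variableStep)", first))
  gr <- rtracklayer::import(path, format = if (is_wig) "wig" else "bedGraph")
  if (length(gr) == 0) stop("empty track: ", path)
  chrom <- as.character(GenomicRanges::seqnames(gr)[1])
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  o <- order(start0)
  start0 <- start0[o]; end0 <- end0[o]
  val <- S4Vectors::mcols(gr)$score[o]
  if (any(start0[-1] < end0[-length(end0)]))
    stop("overlapping intervals in ", path)
  L <- if (is.null(length)) max(end0) else as.integer(length)
  values <- rep(as.numeric(fill), L)
  for (i in seq_along(start0))
    values[(start0[i] + 1):min(end0[i], L)] <- val[i]
  coverage_track(chrom, values, basis)
}

#' Write a track as bedGraph (or fixedStep wiggle)
#'
#' Runs of equal adjacent values are merged; values are written with
#' full precision so that a read back is bitwise identical.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param format `bedgraph` or `wig`.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  v <- track$values
  if (format == "wig") {
    lines <- c(sprintf("fixedStep chrom=%s start=1 step=1 span=1",
                       track$chrom), sprintf("%.17g", v))
    writeLines(lines, path)
    return(invisible(path))
  }
  changed <- c(TRUE, v[-1] != v[-length(v)])
  s <- which(changed) - 1L
  e <- c(s[-1], length(v))
  writeLines(paste(track$chrom, s, e, sprintf("%.17g", v[s + 1L]),
                   sep = "\t"), path)
  invisible(path)
}

## -------------------------------------------------------------- link table

#' Read a protein-link table
#'
#' Tab-separated columns `protein_a`, `protein_b`, `score` (integer
#' evidence score, STRING-style).
#'
#' @param path Input TSV (header optional).
#' @return A `data.frame` of class `link_table`.
#' @export
read_links <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b", "score") %in% names(df))) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df)[1:3] <- c("protein_a", "protein_b", "score")
  }
  link_table(df$protein_a, df$protein_b, df$score)
}

#' Construct a link table
#' @param protein_a,protein_b Protein identifiers.
#' @param score Non-negative integer evidence scores.
#' @return A `data.frame` of class `link_table`.
#' @export
link_table <- function(protein_a, protein_b, score) {
  df <- data.frame(protein_a = as.character(protein_a),
                   protein_b = as.character(protein_b),
                   score = as.integer(score), stringsAsFactors = FALSE)
  if (any(df$protein_a == df$protein_b)) stop("self-links are not allowed")
  if (any(df$score < 0)) stop("link scores must be >= 0")
  class(df) <- c("link_table", "data.frame")
  df
}

#' Write a link table as TSV
#' @param links A [link_table()].
#' @param path Output path.
#' @export
write_links <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
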