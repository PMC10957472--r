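#' @include AllClasses.R mesh.R
NULL

#' Write a mesh as PLY
#'
#' ASCII or binary-little-endian PLY with vertex x/y/z (double) and
#' triangular faces (0-based indices on disk).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path.
#' @param binary write binary little-endian (default ASCII).
#' @return invisibly, \code{path}.
#' @export
writePly <- function(mesh, path, binary = FALSE) {
  v <- mesh@vertices; f <- mesh@faces
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Supports ASCII and binary-little-endian PLY with double or float vertex
#' coordinates and triangular faces.
#'
#' @param path PLY file path.
#' @return a \linkS4class{TriangleMesh}.
#' @export
readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 200L) stop("PLY header not terminated")
  }
  fmt <- sub("^format ([a-z_]+).*", "\\1", grep("^format", header, value = TRUE))
  nV <- as.integer(sub("^element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nF <- as.integer(sub("^element face ", "", grep("^element face", header, value = TRUE)))
  vprops <- header[grep("^property (double|float)", header)]
  sizes <- ifelse(grepl("double", vprops), 8L, 4L)
  if (length(sizes) != 3L) stop("expected exactly 3 vertex coordinate properties")
  if (fmt == "ascii") {
    vl <- readLines(con, n = nV)
    v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "[ \t]+"))), nV, 3L,
                byrow = TRUE)
    fl <- readLines(con, n = nF)
    fparts <- strsplit(trimws(fl), "[ \t]+")
    cnt <- vapply(fparts, function(p) as.integer(p[1L]), integer(1))
    if (any(cnt != 3L)) stop("non-triangular face in PLY")
    f <- matrix(as.integer(unlist(lapply(fparts, `[`, 2:4))), nF, 3L,
                byrow = TRUE) + 1L
  } else if (fmt == "binary_little_endian") {
    v <- matrix(readBin(con, "double", nV * 3L, size = sizes[1L],
                        endian = "little"), nV, 3L, byrow = TRUE)
    f <- matrix(0L, nF, 3L)
    for (i in seq_len(nF)) {
      cnt <- as.integer(readBin(con, "raw", 1L))
      if (cnt != 3L) stop("non-triangular face in PLY")
      f[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  buildMesh(v, f, repairWinding = FALSE)
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeObj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices; f <- mesh@faces
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Triangular faces only; texture/normal references (\code{f a/b/c}) are
#' stripped to the vertex index.
#'
#' @param path OBJ file path.
#' @return a \linkS4class{TriangleMesh}.
#' @export
readObj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- matrix(as.numeric(unlist(strsplit(sub("^v +", "", vl), "[ \t]+"))),
              length(vl), 3L, byrow = TRUE)
  fidx <- lapply(strsplit(sub("^f +", "", fl), "[ \t]+"), function(p)
    as.integer(sub("/.*$", "", p)))
  if (any(lengths(fidx) != 3L)) stop("non-triangular face in OBJ")
  f <- matrix(unlist(fidx), length(fl), 3L, byrow = TRUE)
  buildMesh(v, f, repairWinding = FALSE)
}

## ---- cohort archive -------------------------------------------------------
## Versioned binary container: magic "UPEC", uint32 version, N, M, F counts,
## subject ids (uint32 length + utf8 bytes each), coordinate block (float64,
## subject-major, row-major M x 3 per subject), face block (int32, 0-based).

#' Write a cohort archive
#'
#' Single-file binary container with subject ids, an \code{N x M x 3}
#' float64 coordinate block and the shared face list; versioned header.
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCohortArchive <- function(cohort, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("UPEC"), con)
  d <- dim(cohort@shapes)
  writeBin(as.integer(c(1L, d[1L], d[2L], nrow(cohort@templateFaces),
                        as.integer(cohort@aligned))), con,
           size = 4L, endian = "little")
  for (id in cohort@subjectIds) {
    raw <- charToRaw(enc2utf8(id))
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
  }
  for (i in seq_len(d[1L]))
    writeBin(as.vector(t(cohort@shapes[i, , ])), con, size = 8L,
             endian = "little")
  writeBin(as.integer(t(cohort@templateFaces) - 1L), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' Read a cohort archive
#'
#' @param path archive path written by \code{\link{writeCohortArchive}}.
#' @return a \linkS4class{ShapeCohort}.
#' @export
readCohortArchive <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "UPEC") stop("not a cohort archive (bad magic)")
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  if (hdr[1L] != 1L) stop("unsupported cohort archive version ", hdr[1L])
  N <- hdr[2L]; M <- hdr[3L]; Fn <- hdr[4L]; aligned <- as.logical(hdr[5L])
  ids <- character(N)
  for (i in seq_len(N)) {
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    ids[i] <- rawToChar(readBin(con, "raw", len))
  }
  shapes <- array(0, c(N, M, 3L))
  for (i in seq_len(N))
    shapes[i, , ] <- matrix(readBin(con, "double", M * 3L, size = 8L,
                                    endian = "little"), M, 3L, byrow = TRUE)
  faces <- matrix(readBin(con, "integer", Fn * 3L, size = 4L,
                          endian = "little"), Fn, 3L, byrow = TRUE) + 1L
  methods::new("ShapeCohort", subjectIds = ids, shapes = shapes,
               templateFaces = faces, aligned = aligned)
}

## ---- genotypes ------------------------------------------------------------

#' Write genotypes as VCF
#'
#' Plain-text VCFv4.2 with an \code{INFO} key for the imputation score and a
#' \code{DS} (dosage) FORMAT field; hard-call dosages also get a GT field.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output path (.vcf).
#' @return invisibly, \code{path}.
#' @export
writeVcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=upekit",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation information score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes@subjectIds), collapse = "\t")), con)
  D <- genotypes@dosages
  vm <- genotypes@variants
  hard <- pmin(pmax(round(D), 0), 2)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[hard + 1L], nrow(D))
  gtStr[is.na(D)] <- "./."
  dsStr <- matrix(trimws(formatC(D, format = "g", digits = 15)), nrow(D))
  dsStr[is.na(D)] <- "."
  body <- vapply(seq_len(nrow(D)), function(i) {
    paste(c(vm$chrom[i], format(vm$pos[i], scientific = FALSE, trim = TRUE),
            vm$variant_id[i], vm$nea[i], vm$ea[i], ".", "PASS",
            paste0("INFO=", trimws(formatC(vm$info[i], format = "g", digits = 10))),
            "GT:DS",
            paste0(gtStr[i, ], ":", dsStr[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Reads a VCF into a \linkS4class{GenotypeMatrix}, preferring the \code{DS}
#' FORMAT field and falling back to GT allele counts; the effect allele is
#' ALT. The INFO score is taken from the \code{INFO=} key (1 when absent).
#' Uses \pkg{vcfR} when available, else a plain-text parser.
#'
#' @param path VCF path (may be gzipped with vcfR).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readVcfDosages <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    subjects <- colnames(vcf@gt)[-1L]
    fmtHasDs <- grepl("DS", vcf@gt[, 1L])
    if (all(fmtHasDs)) {
      ds <- vcfR::extract.gt(vcf, element = "DS")
      D <- matrix(suppressWarnings(as.numeric(ds)), nrow(ds),
                  dimnames = dimnames(ds))
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      D <- matrix(vapply(gt, function(g) {
        if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1L]]))
      }, numeric(1)), nrow(gt), dimnames = dimnames(gt))
    }
    infoStr <- fix[, "INFO"]
    info <- suppressWarnings(as.numeric(sub(".*INFO=([0-9.eE+-]+).*", "\\1",
                                            infoStr)))
    info[is.na(info)] <- 1
    vm <- data.frame(variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]), ea = fix[, "ALT"],
                     nea = fix[, "REF"], info = info)
    return(genotypeMatrix(D, vm, subjects))
  }
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1L]]
  subjects <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  parts <- strsplit(body, "\t")
  V <- length(parts)
  D <- matrix(NA_real_, V, length(subjects))
  vm <- data.frame(variant_id = character(V), chrom = character(V),
                   pos = numeric(V), ea = character(V), nea = character(V),
                   info = numeric(V))
  for (i in seq_len(V)) {
    p <- parts[[i]]
    vm$chrom[i] <- p[1L]; vm$pos[i] <- as.numeric(p[2L])
    vm$variant_id[i] <- p[3L]; vm$nea[i] <- p[4L]; vm$ea[i] <- p[5L]
    m <- regmatches(p[8L], regexec("INFO=([0-9.eE+-]+)", p[8L]))[[1L]]
    vm$info[i] <- if (length(m) == 2L) as.numeric(m[2L]) else 1
    fmt <- strsplit(p[9L], ":")[[1L]]
    di <- match("DS", fmt)
    gi <- match("GT", fmt)
    vals <- strsplit(p[-(1:9)], ":")
    if (!is.na(di)) {
      D[i, ] <- suppressWarnings(as.numeric(vapply(vals, `[`, character(1), di)))
    } else if (!is.na(gi)) {
      gt <- vapply(vals, `[`, character(1), gi)
      D[i, ] <- vapply(gt, function(g) {
        if (g %in% c("./.", ".")) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1L]]))
      }, numeric(1))
    }
  }
  genotypeMatrix(D, vm, subjects)
}

#' Write a dosage matrix as TSV with sidecar metadata
#'
#' \code{<stem>.dosages.tsv} (variant_id + one column per subject) and
#' \code{<stem>.variants.tsv} (variant metadata).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param stem output path stem.
#' @return invisibly, the two paths.
#' @export
writeDosageTsv <- function(genotypes, stem) {
  dpath <- paste0(stem, ".dosages.tsv")
  vpath <- paste0(stem, ".variants.tsv")
  dm <- data.frame(variant_id = genotypes@variants$variant_id,
                   genotypes@dosages, check.names = FALSE)
  colnames(dm)[-1L] <- genotypes@subjectIds
  utils::write.table(dm, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genotypes@variants, vpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dpath, vpath))
}

#' Read a dosage matrix from TSV + sidecar metadata
#'
#' @param stem path stem used by \code{\link{writeDosageTsv}}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readDosageTsv <- function(stem) {
  dm <- utils::read.table(paste0(stem, ".dosages.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE)
  vm <- utils::read.table(paste0(stem, ".variants.tsv"), sep = "\t",
                          header = TRUE, colClasses = list(chrom = "character"))
  D <- as.matrix(dm[, -1L, drop = FALSE])
  rownames(D) <- dm$variant_id
  genotypeMatrix(D[match(vm$variant_id, dm$variant_id), , drop = FALSE],
                 vm, colnames(dm)[-1L])
}

#' Write a complete synthetic fixture to disk
#'
#' Writes the cohort archive, genotypes (VCF and TSV), covariates TSV,
#' regions BED (0-based half-open), genes TSV and ground-truth JSON; a
#' fixture directory is self-contained for every pipeline stage.
#'
#' @param sim output of \code{\link{simulateCohort}}.
#' @param dir output directory.
#' @param plyFirst also write the first k subjects as PLY files (default 0).
#' @return invisibly, the directory.
#' @export
writeFixture <- function(sim, dir, plyFirst = 0L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCohortArchive(sim$cohort, file.path(dir, "cohort.upec"))
  writeVcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  writeDosageTsv(sim$genotypes, file.path(dir, "genotypes"))
  utils::write.table(sim$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = sim$regions$chrom,
                    start = format(sim$regions$start, scientific = FALSE, trim = TRUE),
                    end = format(sim$regions$end, scientific = FALSE, trim = TRUE),
                    name = sim$regions$region_id)
  utils::write.table(bed, file.path(dir, "regions.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$factors <- as.data.frame(truth$factors)
  truth$amplitudes <- as.data.frame(truth$amplitudes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       dataframe = "columns")
  if (plyFirst > 0L) {
    dir.create(file.path(dir, "ply"), showWarnings = FALSE)
    for (i in seq_len(min(plyFirst, dim(sim$cohort@shapes)[1L])))
      writePly(cohortMesh(sim$cohort, i),
               file.path(dir, "ply", paste0(sim$cohort@subjectIds[i], ".ply")))
  }
  invisible(dir)
}

#' Read a fixture directory
#'
#' @param dir directory written by \code{\link{writeFixture}}.
#' @return list with cohort, genotypes, covariates, regions, genes, truth.
#' @export
readFixture <- function(dir) {
  cohort <- readCohortArchive(file.path(dir, "cohort.upec"))
  genotypes <- readDosageTsv(file.path(dir, "genotypes"))
  covariates <- utils::read.table(file.path(dir, "covariates.tsv"),
                                  sep = "\t", header = TRUE)
  regions <- readRegionsBed(file.path(dir, "regions.bed"))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, colClasses = list(chrom = "character"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(cohort = cohort, genotypes = genotypes, covariates = covariates,
       regions = regions, genes = genes, truth = truth)
}
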