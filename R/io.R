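# File formats: VCF with per-sample DS dosages, TSV dosage matrices,
# phenotype/covariate tables keyed by sample id, gene annotation (1-based
# inclusive intervals, declared in a header line), flat key=value config.

#' Write cohort genotypes as a dosage VCF
#'
#' One record per SNP, 1-based positions, per-sample dosage in the `DS`
#' FORMAT field.
#'
#' @param cohort a [CsfCohort-class].
#' @param path output path (plain text).
#' @export
writeDosageVcf <- function(cohort, path) {
    info <- snpInfo(cohort)
    G <- dosages(cohort)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
        "##INFO=<ID=EAF,Number=1,Type=Float,Description=\"Effect (ALT) allele frequency\">",
        "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
    for (j in seq_len(nrow(info))) {
        rec <- paste(c(info$chrom[j], info$pos[j], info$snp[j], info$ref[j],
                       info$alt[j], ".", "PASS",
                       sprintf("EAF=%.4g;R2=%.4g", info$eaf[j],
                               info$impQuality[j]),
                       "DS", sprintf("%.3g", G[, j])), collapse = "\t")
        writeLines(rec, con)
    }
    invisible(path)
}

#' Read a dosage VCF into matrix + metadata form
#'
#' @param path VCF path (read via vcfR).
#' @return list with `dosages` (samples x SNPs) and `info`.
#' @export
readDosageVcf <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    getInfo <- function(key) {
        m <- regmatches(fix$INFO <- v@fix[, "INFO"],
                        regexpr(paste0(key, "=[^;]+"), v@fix[, "INFO"]))
        as.numeric(sub(paste0(key, "="), "", m))
    }
    info <- data.frame(snp = fix$ID, chrom = fix$CHROM,
                       pos = as.integer(fix$POS), ref = fix$REF,
                       alt = fix$ALT,
                       eaf = getInfo("EAF"), impQuality = getInfo("R2"),
                       stringsAsFactors = FALSE)
    G <- t(ds)
    colnames(G) <- info$snp
    list(dosages = G, info = info)
}

#' Write/read the samples x SNPs dosage matrix as TSV
#'
#' First column `sample`, one column per SNP.
#' @param cohort a [CsfCohort-class] (or a dosage matrix with rownames).
#' @param path file path.
#' @name dosage-tsv
#' @export
writeDosageTsv <- function(cohort, path) {
    G <- if (is(cohort, "CsfCohort")) dosages(cohort) else as.matrix(cohort)
    out <- data.frame(sample = rownames(G), G, check.names = FALSE)
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}

#' @rdname dosage-tsv
#' @export
readDosageTsv <- function(path) {
    x <- data.table::fread(path, sep = "\t", data.table = FALSE)
    G <- as.matrix(x[, -1L, drop = FALSE])
    rownames(G) <- x[[1L]]
    G
}

#' Write the phenotype side of a cohort as keyed TSV tables
#'
#' Produces `<prefix>_covariates.tsv` (sample, sex, age, ancestry1..5,
#' study, diagnosis) and `<prefix>_biomarkers.tsv` (sample + six markers,
#' empty cells for missing values).
#'
#' @param cohort a [CsfCohort-class].
#' @param prefix path prefix.
#' @export
writeCohortTables <- function(cohort, prefix) {
    sdat <- sampleData(cohort)
    sdat <- data.frame(sample = rownames(sdat), sdat, check.names = FALSE)
    data.table::fwrite(sdat, paste0(prefix, "_covariates.tsv"), sep = "\t")
    bm <- biomarkers(cohort)
    data.table::fwrite(data.frame(sample = rownames(bm), bm,
                                  check.names = FALSE),
                       paste0(prefix, "_biomarkers.tsv"), sep = "\t")
    invisible(prefix)
}

#' Write/read gene annotation intervals
#'
#' Tab-separated gene, chrom, start, end with a header line declaring the
#' 1-based inclusive convention (avoiding 0-based BED ambiguity).
#' @param genes data.frame (gene, chrom, start, end).
#' @param path file path.
#' @name gene-annotation-io
#' @export
writeGeneAnnotation <- function(genes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#coords=1-based-inclusive", con)
    write.table(genes[, c("gene", "chrom", "start", "end")], con,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname gene-annotation-io
#' @export
readGeneAnnotation <- function(path) {
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE,
               colClasses = c(gene = "character", chrom = "character",
                              start = "integer", end = "integer"))
}

#' Write/read a flat key=value configuration file
#'
#' Scalar and vector fields of a [simConfig()] (matrices are flattened
#' row-major with a dim tag).
#' @param config a `SimConfig`.
#' @param path file path.
#' @name config-io
#' @export
writeConfigFile <- function(config, path) {
    fmt <- function(key, val) {
        if (is.matrix(val))
            sprintf("%s=%s;dim=%dx%d", key,
                    paste(signif(t(val), 8), collapse = ","),
                    nrow(val), ncol(val))
        else if (is.data.frame(val) || is.null(val)) NULL
        else sprintf("%s=%s", key, paste(val, collapse = ","))
    }
    lines <- unlist(lapply(names(config), function(k) fmt(k, config[[k]])))
    if (!is.null(config$snpEffects)) {
        se <- config$snpEffects
        lines <- c(lines, sprintf("snpEffects=%s", paste(
            apply(se[, c("snp", "component", "beta", "betaFemale")], 1L,
                  paste, collapse = ":"), collapse = ",")))
    }
    writeLines(lines, path)
    invisible(path)
}

#' @rdname config-io
#' @export
readConfigFile <- function(path) {
    lines <- readLines(path)
    out <- list()
    for (l in lines) {
        key <- sub("=.*", "", l)
        val <- sub("^[^=]*=", "", l)
        if (grepl(";dim=", val)) {
            parts <- strsplit(val, ";dim=")[[1L]]
            dd <- as.integer(strsplit(parts[2L], "x")[[1L]])
            out[[key]] <- matrix(as.numeric(strsplit(parts[1L], ",")[[1L]]),
                                 dd[1L], dd[2L], byrow = TRUE)
        } else if (key == "snpEffects") {
            rows <- strsplit(strsplit(val, ",")[[1L]], ":")
            out[[key]] <- do.call(rbind, lapply(rows, function(r)
                data.frame(snp = as.integer(r[1L]),
                           component = as.integer(r[2L]),
                           beta = as.numeric(r[3L]),
                           betaFemale = as.numeric(r[4L]))))
        } else if (val %in% c("TRUE", "FALSE")) {
            out[[key]] <- as.logical(val)
        } else {
            num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
            out[[key]] <- if (anyNA(num)) strsplit(val, ",")[[1L]] else num
        }
    }
    do.call(simConfig, out[intersect(names(out), names(formals(simConfig)))])
}
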