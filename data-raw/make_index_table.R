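# Regenerates inst/extdata/dinucleotide_properties.tsv: the bundled
# 38-index dinucleotide physicochemical table (SantaLucia 1998 unified
# nearest-neighbour thermodynamics + by-definition compositional
# descriptors). Run from the package root.
bases <- c("A","C","G","T")
din <- paste0(rep(bases, each=4), bases)  # AA AC AG AT CA ... TT
rc <- function(d) chartr("ACGT","TGCA", paste0(substr(d,2,2), substr(d,1,1)))
# SantaLucia (1998) unified nearest-neighbour parameters, 5'->3' steps.
# dG37 kcal/mol, dH kcal/mol, dS cal/(mol K). Complementary steps share values.
nn <- list(
  AA = c(-1.00, -7.9, -22.2),
  AT = c(-0.88, -7.2, -20.4),
  TA = c(-0.58, -7.2, -21.3),
  CA = c(-1.45, -8.5, -22.7),
  GT = c(-1.44, -8.4, -22.4),
  CT = c(-1.28, -7.8, -21.0),
  GA = c(-1.30, -8.2, -22.2),
  CG = c(-2.17, -10.6, -27.2),
  GC = c(-2.24, -9.8, -24.4),
  GG = c(-1.84, -8.0, -19.9))
get_nn <- function(d) if (d %in% names(nn)) nn[[d]] else nn[[rc(d)]]
thermo <- sapply(din, get_nn)  # 3 x 16
b1 <- substr(din,1,1); b2 <- substr(din,2,2)
cnt <- function(b) (b1==b) + (b2==b)
rows <- list(
  santalucia_dG = thermo[1,], santalucia_dH = thermo[2,], santalucia_dS = thermo[3,],
  gc_content = cnt("G")+cnt("C"),
  purine_content = cnt("A")+cnt("G"),
  keto_content = cnt("G")+cnt("T"),
  gc_skew = cnt("G")-cnt("C"),
  at_skew = cnt("A")-cnt("T"),
  count_A = cnt("A"), count_C = cnt("C"), count_G = cnt("G"), count_T = cnt("T"),
  first_A = as.numeric(b1=="A"), first_C = as.numeric(b1=="C"),
  first_G = as.numeric(b1=="G"), first_T = as.numeric(b1=="T"),
  second_A = as.numeric(b2=="A"), second_C = as.numeric(b2=="C"),
  second_G = as.numeric(b2=="G"), second_T = as.numeric(b2=="T"),
  homodimer = as.numeric(b1==b2),
  transition_step = as.numeric(paste0(b1,b2) %in% c("AG","GA","CT","TC")))
for (d in din) rows[[paste0("ind_", d)]] <- as.numeric(din == d)
M <- do.call(rbind, rows); colnames(M) <- din
stopifnot(nrow(M) == 38, !any(apply(M,1,sd)==0))
src <- c(rep("SantaLucia1998_unified_NN",3), rep("composition_by_definition", nrow(M)-3))
df <- data.frame(index=rownames(M), M, source=src, check.names=FALSE)
write.table(df, "inst/extdata/dinucleotide_properties.tsv",
            sep="\t", quote=FALSE, row.names=FALSE)
cat(nrow(df), "indices written\n")
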