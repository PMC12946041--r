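# Build idealized actiCAP-64 montage on a 94 mm sphere.
# Frame: +x right, +y anterior, +z superior (head-centered, mm).
R <- 94

pt <- function(incl, azim) {
  # incl: inclination from vertex (deg); azim: azimuth from anterior midline,
  # negative = left, positive = right
  i <- incl * pi / 180; a <- azim * pi / 180
  c(x = R * sin(i) * sin(a), y = R * sin(i) * cos(a), z = R * cos(i))
}

slerp <- function(p, q, f) {
  # great-circle interpolation between two points on the sphere
  u <- p / sqrt(sum(p^2)); v <- q / sqrt(sum(q^2))
  w <- acos(sum(u * v))
  r <- (sin((1 - f) * w) * u + sin(f * w) * v) / sin(w)
  r * R
}

pos <- list()

# Midline: inclination from vertex, anterior positive azimuth 0, posterior azimuth 180
mid <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
         CPz = -18, Pz = -36, POz = -54, Oz = -72)
for (nm in names(mid)) {
  th <- mid[[nm]]
  pos[[nm]] <- if (th >= 0) pt(th, 0) else pt(-th, 180)
}

# Circumference ring (inclination 72 deg), azimuth steps of 18 deg
circ <- c(Fp1 = -18, AF7 = -36, F7 = -54, FT7 = -72, T7 = -90,
          TP7 = -108, P7 = -126, PO7 = -144, O1 = -162)
for (nm in names(circ)) {
  pos[[nm]] <- pt(72, circ[[nm]])
  rnm <- sub("7$", "8", sub("1$", "2", nm))
  pos[[rnm]] <- pt(72, -circ[[nm]])
}

# Interior rows: quarters of the great-circle arc from the circumference
# electrode to the corresponding midline electrode
rows <- list(
  F  = c("F7", "Fz",  "F5",  "F3",  "F1"),
  FC = c("FT7", "FCz", "FC5", "FC3", "FC1"),
  C  = c("T7", "Cz",  "C5",  "C3",  "C1"),
  CP = c("TP7", "CPz", "CP5", "CP3", "CP1"),
  P  = c("P7", "Pz",  "P5",  "P3",  "P1")
)
mirror <- function(lbl) chartr("13579", "24680", lbl)
for (rw in rows) {
  for (k in 1:3) {
    lbl <- rw[2 + k]
    pos[[lbl]] <- slerp(pos[[rw[1]]], pos[[rw[2]]], k / 4)
    p <- pos[[lbl]]
    pos[[mirror(lbl)]] <- c(-p[1], p[2], p[3])
  }
}
# AF and PO rows: single interior electrode at the arc midpoint
pos[["AF3"]] <- slerp(pos[["AF7"]], pos[["AFz"]], 0.5)
pos[["AF4"]] <- c(-pos[["AF3"]][1], pos[["AF3"]][2:3])
pos[["PO3"]] <- slerp(pos[["PO7"]], pos[["POz"]], 0.5)
pos[["PO4"]] <- c(-pos[["PO3"]][1], pos[["PO3"]][2:3])

# "9/10" ring at inclination 90 (10% below the circumference)
pos[["FT9"]]  <- pt(90, -72);  pos[["FT10"]] <- pt(90, 72)
pos[["PO9"]]  <- pt(90, -144); pos[["PO10"]] <- pt(90, 144)
# TP9/TP10 sit on the mastoids on this cap, below the idealized ring
pos[["TP9"]]  <- pt(115, -108); pos[["TP10"]] <- pt(115, 108)

labels <- c("Fp1","Fp2","F7","F3","Fz","F4","F8","FC5","FC1","FC2","FC6",
            "T7","C3","Cz","C4","T8","TP9","CP5","CP1","CP2","CP6","TP10",
            "P7","P3","Pz","P4","P8","PO9","O1","Oz","O2","PO10",
            "AF7","AF3","AF4","AF8","F5","F1","F2","F6","FT9","FT7","FC3",
            "FC4","FT8","FT10","C5","C1","C2","C6","TP7","CP3","CPz","CP4",
            "TP8","P5","P1","P2","P6","PO7","PO3","POz","PO4","PO8")
stopifnot(length(labels) == 64, all(labels %in% names(pos)))

xyz <- t(vapply(labels, function(l) pos[[l]], numeric(3)))
df <- data.frame(label = labels, x = round(xyz[,1], 3), y = round(xyz[,2], 3),
                 z = round(xyz[,3], 3))
write.table(df, "inst/extdata/acticap64_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# diagnostics: neighbor degrees at 35 mm
D <- as.matrix(dist(xyz))
A <- D < 35 & upper.tri(D) | D < 35 & lower.tri(D)
diag(A) <- FALSE
deg <- rowSums(A)
names(deg) <- labels
cat("mean degree:", mean(deg), "\n")
cat("isolated:", paste(labels[deg == 0], collapse = ", "), "\n")
print(sort(deg))
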