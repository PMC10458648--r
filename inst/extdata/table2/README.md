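# Reference confusion matrices (SMOTE-ENN test sets)

Four 4x4 confusion matrices for the XGBoost, random-forest, KNN and ANN
classifiers evaluated on SMOTE-ENN-balanced soybean lodging test data
(N = 527 each). All files use the standard convention: **rows = actual
class, columns = predicted class**, order NL, ML, HL, SL.

Note on `ann_confusion.csv`: the source table printed the ANN block with
rows and columns swapped relative to the other three classifiers (its
printed "precision" values are row fractions and its "recall" values are
column fractions, the reverse of the XGBoost/RF/KNN blocks). The file here
stores the transpose of the printed block so that all four fixtures share
the rows-actual convention; recomputed recall for NL (22/24 = 0.92) and
overall accuracy (506/527 = 0.96) then agree with the published summary
values. No counts were altered, only the orientation.
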