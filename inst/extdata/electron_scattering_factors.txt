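# Electron atomic scattering factors f_e(q) for neutral atoms (units: Angstrom).
# Five-Gaussian parametrization evaluated as
#   f_e(q) = sum_{i=1..5} c_i * exp(-d_i * q^2),   q = |g| = 1/d_hkl  [1/Angstrom]
# Coefficients are the published five-Gaussian fits of Peng (1996) /
# International Tables for Crystallography Vol. C, Table 4.3.2.2, as
# distributed with the gemmi library (v0.7.4).  The Gaussian widths are
# converted here from the s = sin(theta)/lambda = q/2 convention to the
# q convention (d_i = b_i / 4).
# columns: element c1 d1 c2 d2 c3 d3 c4 d4 c5 d5
H 0.0349 0.133675 0.1201 0.896675 0.197 3.086775 0.0573 4.738125 0.1195 9.656725
C 0.0893 0.061625 0.2563 0.4275 0.757 1.60235 1.0487 4.652825 0.3575 12.563075
N 0.1022 0.061275 0.3219 0.437025 0.7982 1.548125 0.8197 4.34735 0.1715 12.035775
O 0.0974 0.051675 0.2921 0.345375 0.691 1.173575 0.699 3.177625 0.2039 8.11815
F 0.1083 0.051425 0.3175 0.335975 0.6487 1.0697 0.5846 2.8483 0.1421 7.197025
Si 0.2519 0.076875 0.6372 0.50435 1.3795 2.41865 2.5082 7.3436 1.05 20.1183
P 0.2548 0.0727 0.6106 0.4685 1.4541 2.1294 2.3204 6.08585 0.8477 15.8249
S 0.2497 0.067025 0.5628 0.417775 1.3899 1.756675 2.1865 4.884425 0.7715 12.5972
Cl 0.2443 0.0617 0.5397 0.38105 1.3919 1.538425 2.0197 4.167175 0.6621 10.57715
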