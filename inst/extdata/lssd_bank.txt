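# Nine-item severity scale for the liver-stagnation / spleen-deficiency
# pattern in diarrhea-predominant irritable bowel syndrome.
# Two correlated latent factors, simple structure: items i1-i5 load on
# liver_stagnation, items i6-i9 on spleen_deficiency. Four ordered severity
# categories per item; boundary parameters d are strictly decreasing.
# Note: item i9's first discrimination is not reported in the source
# estimates and is fixed at 0, as the simple-structure loading pattern
# requires anyway.
link: probit
dimensions: liver_stagnation spleen_deficiency
categories: none mild middle serious
# item: id | label | a1 a2 | d1 d2 d3
item: i1 | Irritability and susceptibility to rage | 2.03 0 | -0.15 -2.60 -5.39
item: i2 | Depression | 2.19 0 | -0.83 -3.10 -5.91
item: i3 | Discomfort aggravated by mental disorders | 1.29 0 | -0.39 -3.71 -4.65
item: i4 | Sensation of contracture of the lower abdomen | 0.84 0 | -2.51 -4.78 -6.19
item: i5 | Sigh | 1.12 0 | -1.10 -3.29 -5.78
item: i6 | Gastrointestinal rumbling | 0 2.21 | -1.95 -5.66 -7.11
item: i7 | Intestinal flatus from anus | 0 1.48 | -0.95 -3.67 -5.59
item: i8 | Anorexia | 0 0.94 | -2.51 -5.19 -6.30
item: i9 | Discomforts alleviated after defecation | 0 0.98 | -0.49 -2.74 -3.88
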