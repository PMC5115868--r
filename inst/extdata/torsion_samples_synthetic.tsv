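aa	phi	psi	next_is_pro
ALA	-60.6	-39.5	TRUE
ALA	-117.3	77.9	TRUE
ALA	-65.6	-77.4	TRUE
ALA	61.9	42	TRUE
ALA	-60.6	-50.9	TRUE
ALA	47.6	28	TRUE
ALA	-64.5	-42	TRUE
ALA	-106.1	116.8	TRUE
ALA	-72.3	148.2	FALSE
ALA	-111.8	114.7	FALSE
ALA	-110.1	83.2	FALSE
ALA	-81.6	133.6	FALSE
ALA	-136.8	110.4	FALSE
ALA	-58.2	150.8	FALSE
ALA	-44.6	-46.2	FALSE
ALA	-52.9	-44.1	FALSE
ARG	-70.8	-43.7	TRUE
ARG	-70.6	-51	TRUE
ARG	-131.9	97.9	TRUE
ARG	-65.7	-47.8	TRUE
ARG	-95.8	105.6	TRUE
ARG	-121.2	118.5	TRUE
ARG	-141.1	103.5	TRUE
ARG	-110.3	102.5	TRUE
ARG	-66.9	-54.2	FALSE
ARG	47.3	44.4	FALSE
ARG	-116.3	102.3	FALSE
ARG	-118.5	114.8	FALSE
ARG	-61	-40.3	FALSE
ARG	-113.8	131	FALSE
ARG	-111.4	104.8	FALSE
ARG	61.9	43.9	FALSE
ASN	-45.2	-28.4	TRUE
ASN	-70.8	163.8	TRUE
ASN	-56.4	-56.4	TRUE
ASN	-43.1	-47.6	TRUE
ASN	-119.2	107.7	TRUE
ASN	-66.9	152.5	TRUE
ASN	-75.7	158.5	TRUE
ASN	-73.4	157.8	TRUE
ASN	-70	-49.3	FALSE
ASN	-121.2	74	FALSE
ASN	-42.7	-57.8	FALSE
ASN	-122	125.6	FALSE
ASN	-62.2	-57.7	FALSE
ASN	-111.7	102	FALSE
ASN	-59.2	-50.7	FALSE
ASN	-92.5	89.2	FALSE
ASP	-74.7	159.9	TRUE
ASP	-49.1	-37.8	TRUE
ASP	-56.4	-51.3	TRUE
ASP	-42.9	-46.3	TRUE
ASP	-98	126.2	TRUE
ASP	-89.9	154.9	TRUE
ASP	-113.3	87.2	TRUE
ASP	-77.6	151.3	TRUE
ASP	-126	130.7	FALSE
ASP	-63.2	-35.9	FALSE
ASP	-78.1	156.7	FALSE
ASP	-115.1	103.4	FALSE
ASP	-127.4	114	FALSE
ASP	-99.7	119.6	FALSE
ASP	-140.9	140.2	FALSE
ASP	53.6	49.8	FALSE
CYS	-73.5	-41.1	TRUE
CYS	-87.3	157.6	TRUE
CYS	-110.6	101.4	TRUE
CYS	-69.8	158.7	TRUE
CYS	-64.1	137.6	TRUE
CYS	-135.4	138.3	TRUE
CYS	-100.2	121.8	TRUE
CYS	-129.1	121.7	TRUE
CYS	-67.9	-62.3	FALSE
CYS	-140.2	99	FALSE
CYS	-61.4	-55.3	FALSE
CYS	-40.2	-56.8	FALSE
CYS	-59	-41.4	FALSE
CYS	66.6	25.7	FALSE
CYS	-52.2	-45.2	FALSE
CYS	-46.4	-52.2	FALSE
GLN	-135	127.5	TRUE
GLN	-85	157.9	TRUE
GLN	-59.4	-56.8	TRUE
GLN	-137.9	94.8	TRUE
GLN	-126.3	104.4	TRUE
GLN	-132.7	135.1	TRUE
GLN	-60.8	-65.3	TRUE
GLN	-130.5	105	TRUE
GLN	-37.5	-36.1	FALSE
GLN	-70.1	162.5	FALSE
GLN	58.3	33.6	FALSE
GLN	-79.1	128.4	FALSE
GLN	-51.3	-49.9	FALSE
GLN	-60.1	-40.6	FALSE
GLN	-84.7	144.1	FALSE
GLN	-57.5	-32.5	FALSE
GLU	46.9	34.7	TRUE
GLU	-127.7	118.2	TRUE
GLU	-143	128.9	TRUE
GLU	-46.6	-38.8	TRUE
GLU	-35.1	-54	TRUE
GLU	-66.8	163.6	TRUE
GLU	-59.7	-49.1	TRUE
GLU	-120.6	117.1	TRUE
GLU	-65.3	-74.5	FALSE
GLU	-113.1	87.9	FALSE
GLU	-116.7	99.2	FALSE
GLU	-87.7	166	FALSE
GLU	-78.1	145.1	FALSE
GLU	-134.2	88	FALSE
GLU	-63.9	-53.7	FALSE
GLU	-50	-27	FALSE
GLY	91.8	-9.7	TRUE
GLY	92.3	30.2	TRUE
GLY	145.3	166.7	TRUE
GLY	-115.8	144.5	TRUE
GLY	81.2	38.2	TRUE
GLY	98.6	19.4	TRUE
GLY	-149.2	-176.9	TRUE
GLY	117.1	-144.7	TRUE
GLY	-163.5	-158.5	FALSE
GLY	89.9	-179.1	FALSE
GLY	124	29.2	FALSE
GLY	88.9	17.6	FALSE
GLY	95	24.2	FALSE
GLY	69	-5.4	FALSE
GLY	65.7	9.1	FALSE
GLY	62.4	41.8	FALSE
HIS	-57	-46.3	TRUE
HIS	-129.4	97.8	TRUE
HIS	-72.2	160.7	TRUE
HIS	-63.9	135	TRUE
HIS	-68.5	-38.7	TRUE
HIS	-110.9	111.7	TRUE
HIS	-63.9	-52.1	TRUE
HIS	-122.7	115.7	TRUE
HIS	-130.8	123.7	FALSE
HIS	-41.3	-64.8	FALSE
HIS	-103.2	84.6	FALSE
HIS	-52.9	-53.2	FALSE
HIS	-59.9	-36.5	FALSE
HIS	-127	116	FALSE
HIS	-58.9	-50.9	FALSE
HIS	-123.8	96.1	FALSE
ILE	-64.1	133.9	TRUE
ILE	51	29.7	TRUE
ILE	-105.3	102.8	TRUE
ILE	-60.7	-29.1	TRUE
ILE	-133.7	124.5	TRUE
ILE	-91.1	115.2	TRUE
ILE	-103.1	104.4	TRUE
ILE	-69.3	-54.8	TRUE
ILE	-48.2	-57.1	FALSE
ILE	-51.7	-33.4	FALSE
ILE	-122.7	109.1	FALSE
ILE	-112.7	91.7	FALSE
ILE	-41.8	-48.8	FALSE
ILE	-38.8	-52.8	FALSE
ILE	-43.8	-56.8	FALSE
ILE	-104.6	110.8	FALSE
LEU	-77.7	149.8	TRUE
LEU	-102.6	115.5	TRUE
LEU	-59.8	148	TRUE
LEU	-84	143.1	TRUE
LEU	-66.2	-35	TRUE
LEU	-84.4	164.1	TRUE
LEU	64.1	41.2	TRUE
LEU	-49.9	-47.9	TRUE
LEU	-102	103.9	FALSE
LEU	-63.9	-44.9	FALSE
LEU	-75.8	139.9	FALSE
LEU	-110.4	111.7	FALSE
LEU	-69	-51.7	FALSE
LEU	-57.4	163.1	FALSE
LEU	-57.8	-57.3	FALSE
LEU	-79.2	-40.5	FALSE
LYS	-119.6	146.5	TRUE
LYS	-123	109.5	TRUE
LYS	-112.8	144	TRUE
LYS	-60	-28.7	TRUE
LYS	-111.4	134.8	TRUE
LYS	-119.3	110.6	TRUE
LYS	-81.6	156.2	TRUE
LYS	-133.4	114.5	TRUE
LYS	-62.2	-50.4	FALSE
LYS	-45.9	-31.3	FALSE
LYS	-118.4	122.6	FALSE
LYS	40.4	43	FALSE
LYS	-58.9	-51.9	FALSE
LYS	-79.6	142	FALSE
LYS	-40.3	-55.1	FALSE
LYS	-121	95.1	FALSE
MET	-106.7	124.8	TRUE
MET	-63.5	-39.5	TRUE
MET	-62.5	-44.7	TRUE
MET	-66	-44.3	TRUE
MET	-124.1	99.5	TRUE
MET	-121.9	113.9	TRUE
MET	-74.2	141.2	TRUE
MET	-45.4	-46.2	TRUE
MET	-145.5	106.8	FALSE
MET	-90.3	133.4	FALSE
MET	-83.7	138.1	FALSE
MET	-41.2	-38.1	FALSE
MET	-90.7	161.5	FALSE
MET	41.6	36.2	FALSE
MET	-121.7	122	FALSE
MET	-55.4	-46	FALSE
PHE	-127	115.3	TRUE
PHE	-84	160.2	TRUE
PHE	-86.5	136	TRUE
PHE	-65.8	-44.9	TRUE
PHE	-51.8	-41.5	TRUE
PHE	-64.1	139.6	TRUE
PHE	-116.2	112.3	TRUE
PHE	-78.5	163	TRUE
PHE	-144.8	85.9	FALSE
PHE	-61.7	-45.8	FALSE
PHE	-74.4	147.3	FALSE
PHE	-119.7	116.9	FALSE
PHE	-128.3	115.3	FALSE
PHE	-35.1	-44.8	FALSE
PHE	-59.6	-48.7	FALSE
PHE	-66.9	154.6	FALSE
PRO	-53.2	-30.6	TRUE
PRO	-81	147.9	TRUE
PRO	-68.4	156.7	TRUE
PRO	-66.3	149.8	TRUE
PRO	-68	154.4	TRUE
PRO	-52.7	142.9	TRUE
PRO	-55.4	149.7	TRUE
PRO	-70	161.1	TRUE
PRO	-51.7	136	FALSE
PRO	-83.9	135.9	FALSE
PRO	-65.2	-40.7	FALSE
PRO	-66.1	150.8	FALSE
PRO	-53.7	140.2	FALSE
PRO	-69.2	149.7	FALSE
PRO	-73	-21.4	FALSE
PRO	-78.4	-41.7	FALSE
SER	-54.2	-54	TRUE
SER	-121.4	124.3	TRUE
SER	-56.6	138.5	TRUE
SER	50.3	42.3	TRUE
SER	-62.9	161.8	TRUE
SER	-68.7	116.1	TRUE
SER	-75.7	159.3	TRUE
SER	-44.7	-41.6	TRUE
SER	-48.9	-64.9	FALSE
SER	-58.2	-36.5	FALSE
SER	-44.3	-41.3	FALSE
SER	-130.2	115.1	FALSE
SER	-59.8	-56.7	FALSE
SER	-126.1	131.3	FALSE
SER	-52.8	149.7	FALSE
SER	-66.3	-52.9	FALSE
THR	-77.6	-53.2	TRUE
THR	-112.9	114.5	TRUE
THR	-84.7	167.2	TRUE
THR	-47	-49.5	TRUE
THR	-77.6	172	TRUE
THR	-120.4	128.6	TRUE
THR	-83.6	142.6	TRUE
THR	-75.5	164.7	TRUE
THR	-82.7	163.3	FALSE
THR	-79.2	-50.4	FALSE
THR	-121.6	109.3	FALSE
THR	-118.3	93.1	FALSE
THR	-148.5	100.6	FALSE
THR	-63.9	-49.9	FALSE
THR	-45.8	-52.4	FALSE
THR	-45.8	-60.2	FALSE
TRP	-78.8	150.4	TRUE
TRP	-80.4	145.7	TRUE
TRP	-109.9	95.6	TRUE
TRP	-44.7	-44.2	TRUE
TRP	-62.6	-49.4	TRUE
TRP	-126.3	100.7	TRUE
TRP	-123.1	115.7	TRUE
TRP	-41.1	-60.4	TRUE
TRP	-66.7	-65.2	FALSE
TRP	-42.3	-46.9	FALSE
TRP	-51.6	-51.3	FALSE
TRP	-113.6	123	FALSE
TRP	-84.3	107.9	FALSE
TRP	-120.4	103.5	FALSE
TRP	-60.7	-50.5	FALSE
TRP	-57.2	-67.8	FALSE
TYR	-92.5	120.6	TRUE
TYR	-56.1	-49.6	TRUE
TYR	-38.3	-60.8	TRUE
TYR	-137.3	126.5	TRUE
TYR	-67.7	-35.6	TRUE
TYR	-62.7	169.8	TRUE
TYR	-89	151.5	TRUE
TYR	55.4	50.9	TRUE
TYR	-119.7	101.9	FALSE
TYR	-120.8	119.1	FALSE
TYR	-72.9	-50.1	FALSE
TYR	70.3	30.2	FALSE
TYR	-57.5	-43.6	FALSE
TYR	-65.9	-45.9	FALSE
TYR	-124.7	126.2	FALSE
TYR	-47	-34.7	FALSE
VAL	-71.1	-42.6	TRUE
VAL	-71.2	151.5	TRUE
VAL	-59.7	-53	TRUE
VAL	-119.7	130.8	TRUE
VAL	-69	-50.4	TRUE
VAL	-129.8	114.6	TRUE
VAL	-125.4	126.2	TRUE
VAL	-125.8	124.9	TRUE
VAL	-119.1	117.5	FALSE
VAL	59.8	44.4	FALSE
VAL	-48.5	-42.6	FALSE
VAL	-114.6	117	FALSE
VAL	-67.2	153.7	FALSE
VAL	-42.4	-39.8	FALSE
VAL	-110.4	102.3	FALSE
VAL	-97.2	117.9	FALSE
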