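name,full_name,unit,value_kind
a-HBD,alpha hydroxybutyric dehydrogenase,IU/L,integer
GGP,gamma glutamyl transpeptidase,IU/L,integer
LDH,lactate dehydrogenase,mmol/L,real
LDL,low-density lipoprotein,mmol/L,real
HDL,high-density lipoprotein,mmol/L,real
BUN,blood urea nitrogen,mmol/L,real
UA,uric acid,umol/L,integer
TC,total cholesterol,mmol/L,real
TBIL,total bilirubin,umol/L,real
TP,total protein,g/L,integer
TG,triglyceride,mmol/L,real
Alb,albumin,g/L,integer
DBIL,direct bilirubin,umol/L,real
ALP,alkaline phosphatase,IU/L,integer
PI,serum phosphorus,mmol/L,real
SCr,serum creatinine,umol/L,integer
CK,creatine kinase,IU/L,integer
CK-MB,creatine kinase isoenzyme,IU/L,integer
Glu,glucose,mmol/L,real
ALT,alanine aminotransferase,IU/L,integer
AST,aspartate aminotransferase,IU/L,integer
Apo-A1,apolipoprotein A1,g/L,real
Apo-B,apolipoprotein B,g/L,real
Ca,serum calcium,mmol/L,real
Gender,gender,,integer
AGE,age,years,integer
Height,height,cm,real
BMI,body mass index,kg/m2,real
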