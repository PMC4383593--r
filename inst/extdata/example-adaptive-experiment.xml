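<?xml version="1.0" encoding="UTF-8"?>
<experiment>
  <constraints>
    <systemVariables>
      <systemVariable source="de.mpg.de.ASLEyetracker" systemVariableID="sV1" systemVariableName="eyePosIsFixated"/>
      <systemVariable source="de.mpg.de.ASLEyetracker" systemVariableID="sV2" systemVariableName="eyePosX"/>
      <systemVariable source="de.mpg.de.ASLEyetracker" systemVariableID="sV3" systemVariableName="eyePosY"/>
    </systemVariables>
    <constraint constraintID="co1">
      <conditions>
        <condition systemVariableRef="sV1"/>
      </conditions>
      <stimulusActions_else>
        <stimulusAction>
          <insertNewStimulusEvent duration="8" mediaObjectRef="FIXCROSS" shiftFollowingStimulusEvents="true"/>
        </stimulusAction>
      </stimulusActions_else>
    </constraint>
  </constraints>
  <mediaObjects>
    <mediaObject moID="FIXCROSS" name="fixation cross" type="TEXT">
      <contentText>
        <text>+</text>
        <posX>0</posX>
        <posY>0</posY>
      </contentText>
    </mediaObject>
    <mediaObject moID="PicID1" name="1019" type="IMAGE" useConstraint="co1">
      <contentImage>
        <imageFile>pics/1019.jpg</imageFile>
        <posX>0</posX>
        <posY>0</posY>
      </contentImage>
      <regressorAssignment assignToRegressor="REG_NEGDYN" useTransferFunction="tranF1"/>
    </mediaObject>
    <mediaObject moID="PicID2" name="7010" type="IMAGE">
      <contentImage>
        <imageFile>pics/7010.jpg</imageFile>
        <posX>0</posX>
        <posY>0</posY>
      </contentImage>
      <regressorAssignment assignToRegressor="REG_NEUTDYN" useTransferFunction="tranF1"/>
    </mediaObject>
  </mediaObjects>
  <timeTable>
    <stimEvent onset="4000" duration="500" mediaObjectRef="PicID1"/>
    <stimEvent onset="9000" duration="500" mediaObjectRef="PicID2"/>
  </timeTable>
  <transferFunctions>
    <transferFunction transferFunctionID="tranF1" timeOffset="0" durationScaleFactor="0" parametricScaleFactor="1"/>
  </transferFunctions>
  <paradigm ignoreScansAtStart="20" tr="2000">
    <dynamicDesignStruct maxLength="4000000">
      <dynamicTimeBasedRegressor length="4000000" name="neg_dynamic" regressorID="REG_NEGDYN" scaleHeightToZeroMean="false" useRefFct="gloverKernel" useRefFctFirstDerivative="false" useRefFctSecondDerivative="false"/>
      <dynamicTimeBasedRegressor length="4000000" name="neut_dynamic" regressorID="REG_NEUTDYN" scaleHeightToZeroMean="false" useRefFct="gloverKernel" useRefFctFirstDerivative="false" useRefFctSecondDerivative="false"/>
    </dynamicDesignStruct>
  </paradigm>
</experiment>

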